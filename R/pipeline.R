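# End-to-end orchestration over a dataset directory (as produced by
# generate_dataset(), or assembled from external tools' outputs with the
# same file naming), plus the cross-stage statistics reported alongside.

#' Build an anchor table from a homology table and gene coordinates
#'
#' Attaches chromosome and rank to both genes of every homology pair whose
#' genes are present in `genes`. For cross-species pairs the side with the
#' smaller species id (C locale) becomes side A.
#'
#' @param homology Tibble (gene_a, gene_b, score).
#' @param genes Tibble (gene_id, species, chromosome, rank).
#' @param min_score Drop pairs scoring below this (default 0).
#' @return Anchor tibble for [chain_anchors()].
#' @export
anchors_from_homology <- function(homology, genes, min_score = 0) {
  stopifnot_cols(genes, c("gene_id", "species", "chromosome", "rank"))
  info <- genes |> select("gene_id", "species", "chromosome", "rank")
  h <- homology |>
    filter(.data$score >= min_score,
           .data$gene_a %in% info$gene_id, .data$gene_b %in% info$gene_id) |>
    left_join(info, by = c(gene_a = "gene_id")) |>
    rename(species_a = "species", chr_a = "chromosome", rank_a = "rank") |>
    left_join(info, by = c(gene_b = "gene_id")) |>
    rename(species_b = "species", chr_b = "chromosome", rank_b = "rank")
  swap <- h$species_b < h$species_a
  if (any(swap)) {
    tmp <- h[swap, ]
    h[swap, c("gene_a", "species_a", "chr_a", "rank_a",
              "gene_b", "species_b", "chr_b", "rank_b")] <-
      tmp[, c("gene_b", "species_b", "chr_b", "rank_b",
              "gene_a", "species_a", "chr_a", "rank_a")]
  }
  select(h, "gene_a", "species_a", "chr_a", "rank_a",
         "gene_b", "species_b", "chr_b", "rank_b", "score")
}

#' Pearson correlation with t-test p-value
#'
#' Product-moment r with the two-sided p-value from the t transform on
#' n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return One-row tibble: r, statistic, df, p_value.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must have equal length >= 3.")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort("Inputs must not be constant.")
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), statistic = unname(ct$statistic),
         df = unname(ct$parameter), p_value = ct$p.value)
}

#' Cross-tabulate duplication modes by conservation category
#'
#' Counts of each duplication mode within each category, with per-category
#' percentage columns (half-up, 2 decimals).
#'
#' @param calls Tibble (gene_id, mode) from [classify_duplications()].
#' @param categories Tibble (gene_id, category); every called gene must be
#'   categorised.
#' @return Tibble: mode, then `n_<category>` and `pct_<category>` columns.
#' @export
crosstab_dup_by_category <- function(calls, categories) {
  stopifnot_cols(calls, c("gene_id", "mode"))
  stopifnot_cols(categories, c("gene_id", "category"))
  if (nrow(calls) == 0) return(tibble(mode = character(0)))
  missing <- setdiff(calls$gene_id, categories$gene_id)
  if (length(missing) > 0) {
    abort(sprintf("Uncategorised gene(s): %s",
                  paste(c_sort(missing), collapse = ", ")))
  }
  df <- inner_join(calls, categories, by = "gene_id") |>
    count(.data$mode, .data$category) |>
    group_by(.data$category) |>
    mutate(pct = round_half_up(100 * .data$n / sum(.data$n), 2)) |>
    ungroup()
  wide_n <- tidyr::pivot_wider(select(df, "mode", "category", "n"),
                               names_from = "category", values_from = "n",
                               values_fill = 0L, names_prefix = "n_")
  wide_p <- tidyr::pivot_wider(select(df, "mode", "category", "pct"),
                               names_from = "category", values_from = "pct",
                               values_fill = 0, names_prefix = "pct_")
  left_join(wide_n, wide_p, by = "mode") |> arrange(.data$mode)
}

PIPELINE_STAGES <- c("identification", "structure", "classification",
                     "orthogroups", "selection", "duplication", "promoters",
                     "expression")

#' Run the full comparative-genomics pipeline on a dataset directory
#'
#' Executes identification, structure metrics, tree-based classification,
#' orthogroup construction, Ka/Ks estimation with aggregation, collinear
#' block detection with duplication-mode classification, promoter element
#' scanning, and the expression screen, writing each stage's tables under
#' `out_dir` plus a JSON run manifest. Stages communicate only through their
#' tables, so any stage's inputs can be replaced by external tools' outputs
#' that follow the same format.
#'
#' @param data_dir Dataset directory following the [generate_dataset()] file
#'   naming.
#' @param out_dir Output directory.
#' @param stages Character vector of stages to run (default: all, in order).
#' @param params Named list of overrides: evalue_cutoff,
#'   min_protein_length, domain_completeness_fraction, gap_threshold,
#'   min_block_size, max_rank_gap, proximal_max_gap, homolog_min_score,
#'   anchor_min_score, promoter_window, pseudocount.
#' @return A `famscape_run` object: stage results, output paths, manifest.
#' @export
run_pipeline <- function(data_dir, out_dir, stages = PIPELINE_STAGES,
                         params = list()) {
  p <- utils::modifyList(list(
    evalue_cutoff = 1e-10, min_protein_length = 100,
    domain_completeness_fraction = 0.8, gap_threshold = 0.2,
    min_block_size = 10, max_rank_gap = 25, proximal_max_gap = 10,
    homolog_min_score = 85, anchor_min_score = 60,
    promoter_window = 2000, pseudocount = 1.0
  ), params)
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad) > 0) abort(sprintf("Unknown stage(s): %s", paste(bad, collapse = ", ")))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- new.env(parent = emptyenv())
  outputs <- list()
  emit <- function(name, df) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    write_tsv_file(df, path)
    outputs[[name]] <<- path
    invisible(path)
  }
  need <- function(stage, for_stage) {
    if (!stage %in% ls(res)) {
      abort(sprintf("Stage '%s' requires output of stage '%s', which did not run.",
                    for_stage, stage))
    }
    get(stage, envir = res)
  }
  gffs <- list.files(data_dir, "_annotation\\.gff3$", full.names = TRUE)
  sp_names <- sub("_annotation\\.gff3$", "", basename(gffs))
  sp_names <- setdiff(sp_names, "outg")
  read_sp <- function(sp) {
    read_gff_models(file.path(data_dir, paste0(sp, "_annotation.gff3")), species = sp)
  }
  done <- character(0)
  t0 <- Sys.time()

  if ("identification" %in% stages) {
    rosters <- list(); retained <- list()
    for (sp in sp_names) {
      models <- read_sp(sp)
      prot <- read_fasta(file.path(data_dir, paste0(sp, "_proteins.fa")))
      hits <- read_domain_hits(file.path(data_dir, paste0(sp, "_domains.tsv")))
      acc <- filter_candidates(
        hits, tibble(protein_id = names(prot), length = nchar(prot)),
        evalue_cutoff = p$evalue_cutoff,
        min_protein_length = p$min_protein_length,
        domain_completeness_fraction = p$domain_completeness_fraction
      )
      g <- models$genes |> filter(.data$gene_id %in% acc$protein_id)
      fx <- longest_isoform(models$features |> filter(.data$gene_id %in% g$gene_id))
      g <- rename_by_position(g, prefix = paste0(sp, "_FAM"))
      rosters[[sp]] <- g
      retained[[sp]] <- fx
    }
    roster <- bind_rows(rosters)
    assign("identification", list(roster = roster, retained = bind_rows(retained)),
           envir = res)
    emit("roster", roster)
    done <- c(done, "identification")
  }

  if ("structure" %in% stages) {
    idf <- need("identification", "structure")
    metrics <- list()
    for (sp in sp_names) {
      g <- idf$roster |> filter(.data$species == sp)
      if (nrow(g) == 0) next
      cds <- read_fasta(file.path(data_dir, paste0(sp, "_cds.fa")))
      metrics[[sp]] <- structure_metrics(
        g, idf$retained |> filter(.data$gene_id %in% g$gene_id), cds_seqs = cds
      ) |> mutate(species = sp)
    }
    metrics <- bind_rows(metrics)
    assign("structure", metrics, envir = res)
    emit("structure_metrics", metrics)
    done <- c(done, "structure")
  }

  if ("classification" %in% stages) {
    aln <- read_fasta(file.path(data_dir, "protein_alignment.fa"))
    panel <- readr::read_tsv(file.path(data_dir, "reference_panel.tsv"),
                             show_col_types = FALSE)
    trimmed <- trim_alignment(aln, gap_threshold = p$gap_threshold)
    dm <- pairwise_distance(trimmed)
    tree <- neighbor_joining(dm)
    labels <- assign_labels(tree, panel)
    assign("classification", list(tree = tree, labels = labels), envir = res)
    ape::write.tree(tree, file.path(out_dir, "family_nj.nwk"))
    outputs[["tree"]] <- file.path(out_dir, "family_nj.nwk")
    emit("subfamily_labels", labels)
    done <- c(done, "classification")
  }

  if ("orthogroups" %in% stages) {
    idf <- need("identification", "orthogroups")
    hom <- read_homology(file.path(data_dir, "homology.tsv"))
    membership <- build_oggs(hom, idf$roster)
    categories <- classify_oggs(membership, n_species = length(sp_names))
    assign("orthogroups", list(membership = membership, categories = categories),
           envir = res)
    emit("ogg_membership", membership)
    emit("ogg_categories", categories)
    emit("ogg_presence", presence_matrix(membership))
    done <- c(done, "orthogroups")
  }

  if ("selection" %in% stages) {
    og <- need("orthogroups", "selection")
    aln <- read_fasta(file.path(data_dir, "protein_alignment.fa"))
    cds <- unlist(lapply(sp_names, function(sp) {
      read_fasta(file.path(data_dir, paste0(sp, "_cds.fa")))
    }))
    pairs_df <- og$membership |>
      group_by(.data$ogg_id) |>
      filter(dplyr::n() >= 2) |>
      summarise(pair = list(utils::combn(c_sort(.data$gene_id), 2)), .groups = "drop")
    kaks <- list()
    for (i in seq_len(nrow(pairs_df))) {
      prs <- pairs_df$pair[[i]]
      for (j in seq_len(ncol(prs))) {
        a <- prs[1, j]; b <- prs[2, j]
        if (!a %in% names(aln) || !b %in% names(aln)) next
        codon_aln <- backtranslate(aln[[a]], aln[[b]], cds[[a]], cds[[b]])
        kaks[[length(kaks) + 1]] <- ng86(codon_aln, a, b)
      }
    }
    kaks <- bind_rows(kaks)
    cl <- tryCatch(need("classification", "selection"), error = function(e) NULL)
    clusters <- NULL
    if (!is.null(cl)) {
      clusters <- og$membership |>
        inner_join(cl$labels, by = "gene_id") |>
        count(.data$ogg_id, .data$cluster) |>
        group_by(.data$ogg_id) |>
        slice(which.max(.data$n)) |>
        ungroup() |>
        select("ogg_id", "cluster")
    }
    agg <- aggregate_kaks(kaks, select(og$membership, "gene_id", "ogg_id"), clusters)
    assign("selection", list(pairs = kaks, ogg = agg$ogg, cluster = agg$cluster),
           envir = res)
    emit("kaks_pairs", kaks)
    emit("kaks_ogg", agg$ogg)
    if (!is.null(agg$cluster)) emit("kaks_cluster", agg$cluster)
    done <- c(done, "selection")
  }

  if ("duplication" %in% stages) {
    idf <- need("identification", "duplication")
    og <- need("orthogroups", "duplication")
    hom <- read_homology(file.path(data_dir, "homology.tsv"))
    all_genes <- list()
    for (sp in sp_names) {
      all_genes[[sp]] <- read_sp(sp)$genes
    }
    all_genes <- bind_rows(all_genes)
    anchors <- anchors_from_homology(hom, all_genes, min_score = p$anchor_min_score)
    intra <- chain_anchors(anchors |> filter(.data$species_a == .data$species_b),
                           p$min_block_size, p$max_rank_gap)
    cross <- chain_anchors(anchors |> filter(.data$species_a != .data$species_b),
                           p$min_block_size, p$max_rank_gap)
    og_blocks <- NULL
    og_path <- file.path(data_dir, "outgroup_homology.tsv")
    if (file.exists(og_path)) {
      outg <- read_gff_models(file.path(data_dir, "outg_annotation.gff3"),
                              species = "outg")
      og_anchors <- anchors_from_homology(read_homology(og_path),
                                          bind_rows(all_genes, outg$genes))
      og_blocks <- chain_anchors(og_anchors, p$min_block_size, p$max_rank_gap)
    }
    fam_ids <- idf$roster$gene_id
    calls <- list()
    for (sp in sp_names) {
      g <- idf$roster |> filter(.data$species == sp)
      hp <- hom |>
        filter(.data$score >= p$homolog_min_score,
               .data$gene_a %in% g$gene_id, .data$gene_b %in% g$gene_id)
      calls[[sp]] <- classify_duplications(
        select(g, "gene_id", "chromosome", "rank"),
        select(hp, "gene_a", "gene_b"),
        intra_blocks = intra |> filter(.data$species_a == sp),
        outgroup_blocks = og_blocks,
        proximal_max_gap = p$proximal_max_gap
      ) |> mutate(species = sp)
    }
    calls <- bind_rows(calls)
    cats <- og$categories |>
      inner_join(og$membership, by = "ogg_id") |>
      select("gene_id", "category")
    crosstab <- crosstab_dup_by_category(select(calls, "gene_id", "mode"), cats)
    conservation <- synteny_conservation_table(cross, cats)
    assign("duplication", list(intra_blocks = intra, cross_blocks = cross,
                               outgroup_blocks = og_blocks, calls = calls,
                               crosstab = crosstab, conservation = conservation),
           envir = res)
    emit("duplication_calls", calls)
    emit("dup_by_category", crosstab)
    emit("synteny_conservation", conservation)
    flat_blocks <- bind_rows(
      mutate(intra, scope = "intra"), mutate(cross, scope = "cross")
    )
    if (nrow(flat_blocks) > 0) {
      emit("synteny_blocks", flat_blocks |>
             tidyr::unnest("anchors") |>
             select(-dplyr::any_of("start_rank_a")))
    }
    done <- c(done, "duplication")
  }

  if ("promoters" %in% stages) {
    idf <- need("identification", "promoters")
    lib <- readr::read_tsv(file.path(data_dir, "motif_library.tsv"),
                           show_col_types = FALSE)
    hits <- list(); proms <- list()
    for (sp in sp_names) {
      g <- idf$roster |> filter(.data$species == sp)
      if (nrow(g) == 0) next
      genome <- read_fasta(file.path(data_dir, paste0(sp, "_genome.fa")))
      pr <- extract_promoter(g, idf$retained |> filter(.data$gene_id %in% g$gene_id),
                             genome, window = p$promoter_window)
      proms[[sp]] <- pr
      hits[[sp]] <- scan_motifs(pr, lib)
    }
    hits <- bind_rows(hits)
    grouping <- idf$roster |> select("gene_id", group = "species")
    props <- element_proportions(hits, grouping)
    assign("promoters", list(promoters = bind_rows(proms), hits = hits,
                             proportions = props), envir = res)
    emit("element_hits", hits)
    emit("element_proportions_species", props)
    if (nrow(props) >= 2) emit("element_zscores_species", zscore_columns(props))
    done <- c(done, "promoters")
  }

  if ("expression" %in% stages) {
    counts <- readr::read_tsv(file.path(data_dir, "expression_counts.tsv"),
                              show_col_types = FALSE)
    fk <- counts |>
      mutate(fpkm = fpkm(.data$count, .data$length, .data$total_mapped)) |>
      group_by(.data$gene_id, .data$condition) |>
      summarise(mean_fpkm = mean(.data$fpkm), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "condition", values_from = "mean_fpkm")
    conds <- setdiff(names(fk), "gene_id")
    treated_col <- setdiff(conds, "control")[[1]]
    de <- de_screen(
      fk |> rename(treated = all_of(treated_col), control = "control"),
      pseudocount = p$pseudocount
    )
    wide <- counts |>
      mutate(fpkm = fpkm(.data$count, .data$length, .data$total_mapped)) |>
      select("gene_id", "sample", "fpkm") |>
      tidyr::pivot_wider(names_from = "sample", values_from = "fpkm")
    scaled <- row_scale(wide)
    qp <- NULL
    qp_path <- file.path(data_dir, "qpcr_ct.tsv")
    if (file.exists(qp_path)) {
      qp <- ddct(readr::read_tsv(qp_path, show_col_types = FALSE))
      emit("qpcr_folds", qp)
    }
    assign("expression", list(de = de, scaled = scaled, qpcr = qp), envir = res)
    emit("de_calls", de)
    emit("fpkm_row_scaled", scaled)
    done <- c(done, "expression")
  }

  manifest <- list(
    package = as.character(utils::packageVersion("famscape")),
    data_dir = normalizePath(data_dir),
    stages = done,
    parameters = p,
    inputs = as.list(tools::md5sum(list.files(data_dir, full.names = TRUE,
                                              pattern = "\\.(tsv|fa|gff3)$"))),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  outputs[["manifest"]] <- file.path(out_dir, "manifest.json")
  structure(list(
    results = as.list(res), outputs = outputs, manifest = manifest,
    stages = done
  ), class = "famscape_run")
}

#' @export
print.famscape_run <- function(x, ...) {
  cat("famscape pipeline run\n")
  cat("  stages: ", paste(x$stages, collapse = ", "), "\n", sep = "")
  cat("  outputs: ", length(x$outputs), " files\n", sep = "")
  invisible(x)
}

#' Tidy summary of a pipeline run
#'
#' @param x A `famscape_run`.
#' @param ... Unused.
#' @return Tibble with one row per completed stage and its record count.
#' @method tidy famscape_run
#' @export
tidy.famscape_run <- function(x, ...) {
  n_of <- function(stage) {
    r <- x$results[[stage]]
    if (is.null(r)) return(NA_integer_)
    if (is.data.frame(r)) return(nrow(r))
    first_df <- purrr::detect(r, is.data.frame)
    if (is.null(first_df)) NA_integer_ else nrow(first_df)
  }
  tibble(stage = x$stages,
         n_records = vapply(x$stages, n_of, integer(1)))
}

#' One-row overview of a pipeline run
#'
#' @param x A `famscape_run`.
#' @param ... Unused.
#' @return One-row tibble: n_stages, n_family_genes, n_oggs, n_blocks,
#'   n_element_hits, n_responsive.
#' @method glance famscape_run
#' @export
glance.famscape_run <- function(x, ...) {
  r <- x$results
  tibble(
    n_stages = length(x$stages),
    n_family_genes = if (!is.null(r$identification)) nrow(r$identification$roster) else NA_integer_,
    n_oggs = if (!is.null(r$orthogroups)) nrow(r$orthogroups$categories) else NA_integer_,
    n_blocks = if (!is.null(r$duplication)) {
      nrow(r$duplication$intra_blocks) + nrow(r$duplication$cross_blocks)
    } else NA_integer_,
    n_element_hits = if (!is.null(r$promoters)) nrow(r$promoters$hits) else NA_integer_,
    n_responsive = if (!is.null(r$expression)) sum(r$expression$de$responsive) else NA_integer_
  )
}

#' @export
generics::tidy

#' @export
generics::glance
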