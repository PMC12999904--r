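# generate_dataset() body: sequence synthesis, promoter planting, genome
# assembly, and file emission. See synthetic-generate.R for the planning
# helpers.

# position pools along the 300-codon family CDS: subfamily divergence,
# cluster divergence, and member-level planted substitutions
POOL_SUBFAM <- function() list(MEKK = 2:26, ZIK = 27:51, RAF = 52:76)
POOL_CLUSTER <- function(k) (77 + (k - 1) * 6):(77 + (k - 1) * 6 + 5)
POOL_MEMBER <- 161:300

mutate_positions <- function(codons, positions, type) {
  for (p in positions) {
    alt <- mutate_codon(codons[[p]], type)
    if (is.null(alt)) abort(sprintf("Codon %s admits no %s change.", codons[[p]], type))
    codons[[p]] <- alt
  }
  codons
}

exon_plan_for <- function(cluster) {
  # intron-poor MEKK clusters 1-4 (single exon), intron-rich elsewhere
  if (cluster <= 4) list(n_exons = 1L, intron_range = c(0, 0))
  else if (cluster == 5) list(n_exons = 8L, intron_range = c(80, 200))
  else if (cluster <= 7) list(n_exons = 5L, intron_range = c(150, 500))
  else list(n_exons = 8L, intron_range = c(500, 2500))
}

realize_consensus <- function(consensus) {
  paste0(vapply(strsplit(toupper(consensus), "")[[1]],
                function(ch) substr(IUPAC_SETS[[ch]], 1, 1), ""), collapse = "")
}

# iteratively scrub every library match (both strands) from a random
# background; the filler tract contains no A/G pair patterns used by the
# library, so convergence is fast
clean_background <- function(n, library) {
  seq <- random_dna(n)
  pats <- c(library$consensus, revcomp(library$consensus))
  lens <- rep(nchar(library$consensus), 2)
  for (iter in 1:30) {
    dirty <- FALSE
    for (k in seq_along(pats)) {
      st <- iupac_match_starts(seq, pats[[k]])
      if (length(st) > 0) {
        dirty <- TRUE
        for (s in st) {
          filler <- substr(strrep("CCTT", ceiling(lens[[k]] / 4) + 1), 1, lens[[k]])
          substr(seq, s, s + lens[[k]] - 1) <- filler
        }
      }
    }
    if (!dirty) return(seq)
  }
  abort("Could not scrub motif matches from background within 30 passes.")
}

build_promoter <- function(background, plan_elements, plan_strands, positions, library) {
  seq <- background
  truth <- list()
  for (i in seq_along(plan_elements)) {
    el <- plan_elements[[i]]
    row <- library[library$element == el, ]
    ins <- realize_consensus(row$consensus[[1]])
    strand <- plan_strands[[i]]
    if (ins == revcomp(ins)) strand <- "+" # palindromes report as plus
    payload <- if (strand == "+") ins else revcomp(ins)
    substr(seq, positions[[i]], positions[[i]] + nchar(ins) - 1) <- payload
    truth[[i]] <- tibble(element = el, class = row$class[[1]],
                         start = as.integer(positions[[i]]), strand = strand)
  }
  list(sequence = seq, truth = bind_rows(truth))
}

#' Generate a synthetic multi-species dataset with planted ground truth
#'
#' Writes, per species: genome FASTA, CDS/protein FASTA, GFF3 annotation and
#' a domain-hit table; plus shared homology and outgroup-homology tables, an
#' ungapped family protein alignment with cluster references, a reference
#' panel, promoter FASTA, motif library, expression counts and qPCR Ct
#' tables, and all truth tables (under `truth/`). Repeated calls with an
#' equal config produce byte-identical files.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list: `dir`, `files` (named paths), `truth` (list of
#'   truth tibbles), `config`.
#' @export
generate_dataset <- function(config = synth_config(), out_dir) {
  cfg <- config
  if (!inherits(cfg, "synth_config")) abort("`config` must come from synth_config().")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  N <- cfg$n_species; K <- cfg$chromosomes_per_species
  GPC <- cfg$genes_per_chromosome; L <- cfg$block_length
  species <- sprintf("sp%02d", seq_len(N))
  lib <- default_motif_library()

  oggs <- plan_oggs(cfg)
  events <- plan_events(cfg, oggs)
  cr_oggs <- cross_block_oggs(cfg, oggs, events)

  layouts <- stats::setNames(lapply(seq_len(N), function(i) {
    layout_species(cfg, species[[i]], oggs, events, cr_oggs,
                   seed = sub_seed(cfg$seed, 100 + i))
  }), species)
  fam <- bind_rows(lapply(layouts, `[[`, "fam"))

  # outgroup layout: one chromosome of background genes hosting the
  # ancestral-locus windows for TRD events
  trd_events <- events$event[events$mode == "TRD"]
  outg_n <- length(trd_events) * L + 10L
  outg_genes <- sprintf("outg_bg_s%03d", seq_len(outg_n))

  ## ---- sequences --------------------------------------------------------
  seqs <- with_seed(sub_seed(cfg$seed, 2), {
    root <- random_codons(L_FAM)
    pools <- POOL_SUBFAM()
    subfam_anc <- lapply(stats::setNames(names(pools), names(pools)), function(sf) {
      mutate_positions(root, pools[[sf]], "any")
    })
    cluster_anc <- lapply(1:14, function(k) {
      mutate_positions(subfam_anc[[subfamily_of_cluster(k)]], POOL_CLUSTER(k), "any")
    })
    member_cds <- list(); pair_counts <- list()
    for (i in seq_len(nrow(oggs))) {
      og <- oggs[i, ]
      anc <- cluster_anc[[og$cluster]]
      members <- fam$gene_id[fam$ogg_id == og$ogg_id]
      members <- c_sort(members)
      m <- length(members)
      if (m == 0) next
      sites <- syn_site_table()
      S_anc <- sum(sites[anc]); N_anc <- 3 * L_FAM - S_anc
      s_i <- 3L
      n_i <- max(1L, as.integer(round(og$omega_target * s_i * N_anc / S_anc)))
      while (m * (s_i + n_i) > length(POOL_MEMBER) && s_i > 1L) {
        s_i <- s_i - 1L
        n_i <- max(1L, as.integer(round(og$omega_target * s_i * N_anc / S_anc)))
      }
      if (m * (s_i + n_i) > length(POOL_MEMBER)) {
        n_i <- max(1L, length(POOL_MEMBER) %/% m - s_i)
      }
      pool <- POOL_MEMBER
      muts <- list()
      for (g in members) {
        syn_ok <- pool[vapply(pool, function(p) {
          length(codon_neighbors()[[anc[[p]]]]$syn) > 0
        }, logical(1))]
        sp_pos <- sample(syn_ok, s_i)
        pool <- setdiff(pool, sp_pos)
        non_ok <- pool[vapply(pool, function(p) {
          length(codon_neighbors()[[anc[[p]]]]$nonsyn) > 0
        }, logical(1))]
        np_pos <- sample(non_ok, n_i)
        pool <- setdiff(pool, np_pos)
        cds <- mutate_positions(anc, sp_pos, "syn")
        cds <- mutate_positions(cds, np_pos, "nonsyn")
        member_cds[[g]] <- cds
        muts[[g]] <- list(s = s_i, n = n_i)
      }
      if (m >= 2) {
        prs <- utils::combn(members, 2)
        pair_counts[[og$ogg_id]] <- tibble(
          gene_a = prs[1, ], gene_b = prs[2, ],
          syn = vapply(seq_len(ncol(prs)), function(j) {
            muts[[prs[1, j]]]$s + muts[[prs[2, j]]]$s
          }, numeric(1)),
          nonsyn = vapply(seq_len(ncol(prs)), function(j) {
            muts[[prs[1, j]]]$n + muts[[prs[2, j]]]$n
          }, numeric(1))
        )
      }
    }
    refs <- lapply(stats::setNames(1:14, sprintf("AtREF_C%02d", 1:14)), function(k) {
      mutate_positions(cluster_anc[[k]], sample(POOL_MEMBER, 2), "any")
    })
    list(member_cds = member_cds, refs = refs, pair_counts = bind_rows(pair_counts))
  })

  ## ---- background / violator CDS ---------------------------------------
  viol <- list()
  bg_cds <- with_seed(sub_seed(cfg$seed, 3), {
    out <- list()
    for (sp in species) {
      grid <- layouts[[sp]]$grid
      fam_sp <- layouts[[sp]]$fam
      for (ch in seq_len(K)) {
        for (s in seq_len(GPC)) {
          gid <- grid[[ch]][[s]]
          if (!gid %in% fam_sp$gene_id) out[[gid]] <- random_codons(60)
        }
      }
      # three filter violators: weak E-value, short protein, partial domain
      bg_ids <- grep(sprintf("^%s_bg_c%d_", sp, K), names(out), value = TRUE)
      pick <- utils::tail(bg_ids, 3)
      out[[pick[[1]]]] <- random_codons(150)
      out[[pick[[2]]]] <- random_codons(90)
      out[[pick[[3]]]] <- random_codons(150)
      viol[[sp]] <- tibble(
        gene_id = pick, species = sp,
        violation = c("evalue", "short_protein", "partial_domain")
      )
    }
    out
  })
  violators <- bind_rows(viol)

  ## ---- promoters --------------------------------------------------------
  fam_sorted <- fam[c_order(fam$gene_id), , drop = FALSE]
  plan_el <- rep(names(cfg$motif_plan), times = cfg$motif_plan)
  k_ins <- length(plan_el)
  win <- cfg$promoter_window
  if (k_ins > 0 && win < 300 + 30 * k_ins) {
    abort("promoter_window too small for the requested motif_plan.")
  }
  prom <- with_seed(sub_seed(cfg$seed, 4), {
    pool_bg <- lapply(1:7, function(i) clean_background(win, lib))
    base_pos <- if (k_ins > 0) {
      150L + (seq_len(k_ins) - 1L) * ((win - 300L) %/% max(k_ins, 1L))
    } else integer(0)
    strands <- if (k_ins > 0) rep(c("+", "-"), length.out = k_ins) else character(0)
    seqs_out <- character(nrow(fam_sorted))
    truth_out <- vector("list", nrow(fam_sorted))
    jitters <- lapply(seq_len(nrow(fam_sorted)), function(i) {
      if (k_ins > 0) sample(0:19, k_ins, replace = TRUE) else integer(0)
    })
    for (i in seq_len(nrow(fam_sorted))) {
      bg <- pool_bg[[(i - 1) %% 7 + 1]]
      built <- build_promoter(bg, plan_el, strands, base_pos + jitters[[i]], lib)
      seqs_out[[i]] <- built$sequence
      truth_out[[i]] <- mutate(built$truth, gene_id = fam_sorted$gene_id[[i]])
    }
    list(seqs = seqs_out, truth = truth_out)
  })
  prom_tb <- tibble(gene_id = fam_sorted$gene_id, sequence = prom$seqs)
  motif_truth <- bind_rows(prom$truth)
  if (k_ins > 0) {
    # verify the planted hit set is exactly what scanning reports; re-jitter
    # unlucky placements (e.g. junction-made matches) deterministically
    for (attempt in 1:40) {
      got <- scan_motifs(prom_tb, lib) |>
        select("gene_id", "element", "start", "strand") |>
        arrange(.data$gene_id, .data$start, .data$element)
      want <- motif_truth |>
        select("gene_id", "element", "start", "strand") |>
        arrange(.data$gene_id, .data$start, .data$element)
      if (identical(as.data.frame(got), as.data.frame(want))) break
      bad_genes <- union(
        anti_join(got, want, by = names(got))$gene_id,
        anti_join(want, got, by = names(got))$gene_id
      )
      if (attempt == 40) {
        abort("Could not realise a clean planted-motif layout after 40 attempts.")
      }
      redo <- with_seed(sub_seed(cfg$seed, 40 + attempt), {
        lapply(bad_genes, function(g) {
          i <- which(prom_tb$gene_id == g)
          bg <- clean_background(win, lib)
          pos <- 150L + (seq_len(k_ins) - 1L) * ((win - 300L) %/% k_ins) +
            sample(0:19, k_ins, replace = TRUE)
          built <- build_promoter(bg, plan_el,
                                  rep(c("+", "-"), length.out = k_ins), pos, lib)
          list(i = i, seq = built$sequence,
               truth = mutate(built$truth, gene_id = g))
        })
      })
      for (r in redo) {
        prom_tb$sequence[[r$i]] <- r$seq
        motif_truth <- motif_truth |> filter(.data$gene_id != prom_tb$gene_id[[r$i]])
        motif_truth <- bind_rows(motif_truth, r$truth)
      }
    }
  }
  prom_seq <- stats::setNames(prom_tb$sequence, prom_tb$gene_id)

  ## ---- genome assembly + annotation ------------------------------------
  all_cds_str <- c(
    vapply(seqs$member_cds, paste0, "", collapse = ""),
    vapply(bg_cds, paste0, "", collapse = "")
  )
  asm <- with_seed(sub_seed(cfg$seed, 5), {
    genes_rows <- list(); feat_rows <- list(); genomes <- list()
    retained <- list()
    fam_idx <- stats::setNames(seq_len(nrow(fam)), fam$gene_id)
    ogg_by_id <- stats::setNames(seq_len(nrow(oggs)), oggs$ogg_id)
    for (sp in species) {
      grid <- layouts[[sp]]$grid
      chrs <- list()
      for (ch in seq_len(K)) {
        pieces <- list(); pos <- 0L
        for (s in seq_len(GPC)) {
          gid <- grid[[ch]][[s]]
          is_fam <- gid %in% names(fam_idx)
          cds <- all_cds_str[[gid]]
          strand <- if (stats::runif(1) < 0.7) "+" else "-"
          if (is_fam) {
            og <- oggs[ogg_by_id[[fam$ogg_id[[fam_idx[[gid]]]]]], ]
            ep <- exon_plan_for(og$cluster)
            upstream <- prom_seq[[gid]]
          } else {
            ep <- list(n_exons = 1L, intron_range = c(0, 0))
            upstream <- random_dna(60)
          }
          ne <- ep$n_exons
          cds_len <- nchar(cds)
          sizes <- rep(cds_len %/% ne, ne)
          sizes[ne] <- sizes[ne] + cds_len %% ne
          introns <- if (ne > 1) {
            rlogunif_int(ne - 1, ep$intron_range[1], ep$intron_range[2])
          } else integer(0)
          # sense-coordinate exon intervals within the gene body
          exon_b <- integer(ne); exon_e <- integer(ne); cur <- 1L
          body_parts <- list(); cpos <- 1L
          for (x in seq_len(ne)) {
            exon_b[[x]] <- cur
            exon_e[[x]] <- cur + sizes[[x]] - 1L
            body_parts[[length(body_parts) + 1]] <- substr(cds, cpos, cpos + sizes[[x]] - 1L)
            cpos <- cpos + sizes[[x]]
            cur <- exon_e[[x]] + 1L
            if (x < ne) {
              body_parts[[length(body_parts) + 1]] <- random_dna(introns[[x]])
              cur <- cur + introns[[x]]
            }
          }
          body <- paste0(unlist(body_parts), collapse = "")
          lb <- nchar(body)
          spacer <- random_dna(60)
          if (strand == "+") {
            block <- paste0(spacer, upstream, body)
            gstart <- pos + nchar(spacer) + nchar(upstream) + 1L
            e_starts <- gstart + exon_b - 1L
            e_ends <- gstart + exon_e - 1L
            gend <- gstart + lb - 1L
          } else {
            block <- paste0(spacer, revcomp(paste0(upstream, body)))
            gstart <- pos + nchar(spacer) + 1L
            e_starts <- gstart + lb - exon_e
            e_ends <- gstart + lb - exon_b
            gend <- gstart + lb - 1L
          }
          pieces[[length(pieces) + 1]] <- block
          pos <- pos + nchar(block)
          genes_rows[[length(genes_rows) + 1]] <- tibble(
            gene_id = gid, species = sp, chromosome = paste0("chr", ch),
            start = gstart, end = gend, strand = strand, rank = s
          )
          tx1 <- paste0(gid, ".t1")
          ord <- order(e_starts)
          feat_rows[[length(feat_rows) + 1]] <- tibble(
            gene_id = gid, transcript_id = tx1,
            type = rep(c("exon", "cds"), each = ne),
            start = rep(e_starts[ord], 2), end = rep(e_ends[ord], 2)
          )
          retained[[length(retained) + 1]] <- tibble(gene_id = gid, transcript_id = tx1)
          # a shorter second isoform for every fifth multi-exon family gene
          if (is_fam && ne >= 2 && (fam_idx[[gid]] %% 5 == 0)) {
            keep_x <- seq_len(ne - 1)
            es <- e_starts[keep_x]; ee <- e_ends[keep_x]
            o2 <- order(es)
            feat_rows[[length(feat_rows) + 1]] <- tibble(
              gene_id = gid, transcript_id = paste0(gid, ".t2"),
              type = rep(c("exon", "cds"), each = ne - 1),
              start = rep(es[o2], 2), end = rep(ee[o2], 2)
            )
          }
        }
        chrs[[paste0("chr", ch)]] <- paste0(unlist(pieces), collapse = "")
      }
      genomes[[sp]] <- unlist(chrs)
    }
    list(genes = bind_rows(genes_rows), features = bind_rows(feat_rows),
         genomes = genomes, retained = bind_rows(retained))
  })

  ## ---- outgroup annotation ---------------------------------------------
  outg_genes_tb <- tibble(
    gene_id = outg_genes, species = "outg", chromosome = "chr1",
    start = 200L * (seq_len(outg_n) - 1L) + 1L,
    end = 200L * (seq_len(outg_n) - 1L) + 180L,
    strand = "+", rank = seq_len(outg_n)
  )
  outg_feat <- tibble(
    gene_id = outg_genes, transcript_id = paste0(outg_genes, ".t1"),
    type = "exon", start = outg_genes_tb$start, end = outg_genes_tb$end
  ) |>
    bind_rows(tibble(
      gene_id = outg_genes, transcript_id = paste0(outg_genes, ".t1"),
      type = "cds", start = outg_genes_tb$start, end = outg_genes_tb$end
    ))

  ## ---- planted blocks + homology ---------------------------------------
  hom_extra <- list(); outg_hom <- list(); block_truth <- list()
  with_seed(sub_seed(cfg$seed, 6), {
    gid_at <- function(sp, ch, slot) layouts[[sp]]$grid[[ch]][[slot]]
    add_block <- function(kind, sa, sb, cha, chb, slots_a, slots_b, ranks_b = NULL) {
      bid <- sprintf("PB%02d", length(block_truth) + 1)
      rows <- lapply(seq_along(slots_a), function(o) {
        ga <- gid_at(sa, cha, slots_a[[o]])
        gb <- if (sb == "outg") outg_genes[[slots_b[[o]]]] else gid_at(sb, chb, slots_b[[o]])
        tibble(block_id = bid, kind = kind, species_a = sa, species_b = sb,
               chr_a = paste0("chr", cha),
               chr_b = if (sb == "outg") "chr1" else paste0("chr", chb),
               offset = o, gene_a = ga, rank_a = slots_a[[o]],
               gene_b = gb, rank_b = slots_b[[o]])
      })
      block_truth[[bid]] <<- bind_rows(rows)
      bid
    }
    win_of <- function(sp, kind, tag) {
      w <- keep(layouts[[sp]]$windows, function(x) x$kind == kind && x$tag == tag)
      if (length(w) != 1) abort("Internal: window lookup failed.")
      w[[1]]
    }
    mid <- ceiling(L / 2)
    for (i in seq_len(nrow(events))) {
      e <- events[i, ]
      if (e$mode == "WGD") {
        wa <- win_of(e$species, "wgd_a", e$event)
        wb <- win_of(e$species, "wgd_b", e$event)
        add_block("intra", e$species, e$species, wa$chr, wb$chr, wa$slots, wb$slots)
        for (o in seq_len(L)) {
          if (o == mid) next # the family pair is already a true homology pair
          hom_extra[[length(hom_extra) + 1]] <- tibble(
            gene_a = gid_at(e$species, wa$chr, wa$slots[[o]]),
            gene_b = gid_at(e$species, wb$chr, wb$slots[[o]]),
            score = stats::runif(1, 61, 80)
          )
        }
      } else if (e$mode == "TRD") {
        w <- win_of(e$species, "outgroup", e$event)
        idx <- which(trd_events == e$event)
        slots_b <- ((idx - 1) * L + 1):(idx * L)
        add_block("outgroup", e$species, "outg", w$chr, NA, w$slots, slots_b)
        for (o in seq_len(L)) {
          outg_hom[[length(outg_hom) + 1]] <- tibble(
            gene_a = gid_at(e$species, w$chr, w$slots[[o]]),
            gene_b = outg_genes[[slots_b[[o]]]],
            score = stats::runif(1, 70, 90)
          )
        }
      }
    }
    for (j in seq_len(cfg$n_cross_blocks)) {
      pair <- sprintf("sp%02d", c(2 * j - 1, 2 * j))
      wa <- win_of(pair[[1]], "cross", j)
      wb <- win_of(pair[[2]], "cross", j)
      add_block("cross", pair[[1]], pair[[2]], wa$chr, wb$chr, wa$slots, wb$slots)
      offs <- unique(pmin(L, pmax(1, round(L * c(0.2, 0.5, 0.8)))))
      for (o in seq_len(L)) {
        if (o %in% offs) next # family same-OGG anchors come from true pairs
        hom_extra[[length(hom_extra) + 1]] <- tibble(
          gene_a = gid_at(pair[[1]], wa$chr, wa$slots[[o]]),
          gene_b = gid_at(pair[[2]], wb$chr, wb$slots[[o]]),
          score = stats::runif(1, 61, 80)
        )
      }
    }
  })

  homology <- with_seed(sub_seed(cfg$seed, 7), {
    rows <- list()
    copies <- fam[fam$role == "copy", , drop = FALSE]
    copy_key <- paste(copies$species, copies$ogg_id)
    for (i in seq_len(nrow(oggs))) {
      og <- oggs[i, ]
      members <- c_sort(fam$gene_id[fam$ogg_id == og$ogg_id])
      if (length(members) < 2) next
      sp_of <- stats::setNames(fam$species[match(members, fam$gene_id)], members)
      role_of <- stats::setNames(fam$role[match(members, fam$gene_id)], members)
      buddy <- stats::setNames(rep(NA_character_, length(members)), members)
      for (g in members[role_of[members] == "copy"]) {
        cand <- setdiff(og$presence[[1]], sp_of[[g]])
        cand <- cand[!paste(cand, og$ogg_id) %in% copy_key]
        if (length(cand) > 0) buddy[[g]] <- cand[[1]]
      }
      prs <- utils::combn(members, 2)
      for (jj in seq_len(ncol(prs))) {
        a <- prs[1, jj]; b <- prs[2, jj]
        a_copy <- role_of[[a]] == "copy"; b_copy <- role_of[[b]] == "copy"
        score <- if (!a_copy && !b_copy) {
          stats::runif(1, 92, 95)
        } else if (a_copy && !b_copy) {
          if (!is.na(buddy[[a]]) && sp_of[[b]] == buddy[[a]]) stats::runif(1, 96, 97)
          else stats::runif(1, 90, 91)
        } else if (!a_copy && b_copy) {
          if (!is.na(buddy[[b]]) && sp_of[[a]] == buddy[[b]]) stats::runif(1, 96, 97)
          else stats::runif(1, 90, 91)
        } else stats::runif(1, 90, 91)
        rows[[length(rows) + 1]] <- tibble(gene_a = a, gene_b = b, score = score)
      }
    }
    # decoy pairs between conserved-orthogroup genes of different groups
    cons_members <- fam$gene_id[fam$ogg_id %in% oggs$ogg_id[oggs$category == "conserved"] &
                                  fam$role == "member"]
    cons_members <- c_sort(cons_members)
    n_dec <- min(cfg$n_oggs, length(cons_members) %/% 2)
    if (n_dec > 0) {
      perm <- sample(cons_members, 2 * n_dec)
      ogg_of <- stats::setNames(fam$ogg_id, fam$gene_id)
      for (t in seq_len(n_dec)) {
        a <- perm[[2 * t - 1]]; b <- perm[[2 * t]]
        if (ogg_of[[a]] == ogg_of[[b]]) next
        rows[[length(rows) + 1]] <- tibble(gene_a = a, gene_b = b,
                                           score = stats::runif(1, 30, 60))
      }
    }
    bind_rows(c(rows, hom_extra))
  })
  outg_homology <- if (length(outg_hom) > 0) bind_rows(outg_hom) else {
    tibble(gene_a = character(0), gene_b = character(0), score = numeric(0))
  }

  ## ---- domain hits ------------------------------------------------------
  domains <- with_seed(sub_seed(cfg$seed, 8), {
    rows <- list()
    for (sp in species) {
      fg <- c_sort(fam$gene_id[fam$species == sp])
      rows[[sp]] <- tibble(
        protein_id = fg, model_id = "PF00069",
        evalue = 10^-stats::runif(length(fg), 15, 30),
        model_len = 260L, model_from = 1L, model_to = 260L,
        ali_from = 1L, ali_to = 260L
      )
      v <- violators[violators$species == sp, ]
      rows[[paste0(sp, "_v")]] <- tibble(
        protein_id = v$gene_id, model_id = "PF00069",
        evalue = c(1e-5, 1e-30, 1e-30),
        model_len = 260L, model_from = 1L,
        model_to = c(260L, 260L, 130L),
        ali_from = 1L, ali_to = c(260L, 90L, 130L)
      )
    }
    bind_rows(rows)
  })

  ## ---- expression + qPCR ------------------------------------------------
  expr_genes <- c_sort(fam$gene_id[fam$species == species[[1]]])
  expr <- with_seed(sub_seed(cfg$seed, 9), {
    n <- length(expr_genes)
    n_de <- ceiling(cfg$de_frac * n)
    de_idx <- sample.int(n, n_de)
    lfc <- stats::runif(n, -0.5, 0.5)
    lfc[de_idx] <- stats::runif(n_de, 1.5, 3.5) *
      rep_len(c(1, -1), n_de)
    baseline <- exp(stats::runif(n, log(10), log(200)))
    total <- 2e7; len <- 3 * L_FAM
    rows <- list()
    for (r in 1:3) {
      for (cond in c("control", "drought")) {
        mean_fpkm <- if (cond == "control") baseline else baseline * 2^lfc
        f <- mean_fpkm * stats::runif(n, 0.97, 1.03)
        rows[[paste(cond, r)]] <- tibble(
          gene_id = expr_genes, sample = sprintf("%s_r%d", cond, r),
          condition = cond, replicate = r,
          count = as.integer(round(f * len * total / 1e9)),
          length = len, total_mapped = total
        )
      }
    }
    list(counts = bind_rows(rows),
         truth = tibble(gene_id = expr_genes, log2fc = lfc,
                        responsive = abs(lfc) > 1))
  })
  qpcr <- with_seed(sub_seed(cfg$seed, 10), {
    g3 <- utils::head(expr_genes, 3)
    tps <- c(0, 1, 3, 6, 12, 24)
    rows <- list()
    for (gi in seq_along(g3)) {
      peak <- c(4, 2.5, 1.5)[[gi]]
      lfc_t <- peak * tps / 24
      for (ti in seq_along(tps)) {
        for (r in 1:3) {
          ct_ref <- 20 + stats::rnorm(1, 0, 0.05)
          rows[[length(rows) + 1]] <- tibble(
            gene_id = g3[[gi]], condition = "salt", timepoint = tps[[ti]],
            replicate = r,
            ct_target = ct_ref + 5 - lfc_t[[ti]] + stats::rnorm(1, 0, 0.05),
            ct_reference = ct_ref
          )
        }
      }
    }
    bind_rows(rows)
  })

  ## ---- truth tables -----------------------------------------------------
  dup_truth <- tibble(gene_id = fam$gene_id, species = fam$species,
                      mode = "singleton")
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    member <- sprintf("%s_%s", e$species, e$ogg_id)
    copy <- sprintf("%s_%s_d1", e$species, e$ogg_id)
    modes <- switch(e$mode,
      WGD = c(member = "WGD", copy = "WGD"),
      TD = c(member = "TD", copy = "TD"),
      PD = c(member = "PD", copy = "PD"),
      TRD = c(member = "DSD", copy = "TRD"), # ancestral copy keeps synteny
      DSD = c(member = "DSD", copy = "DSD")
    )
    dup_truth$mode[dup_truth$gene_id == member] <- modes[["member"]]
    dup_truth$mode[dup_truth$gene_id == copy] <- modes[["copy"]]
  }

  truth <- list(
    roster = fam |>
      left_join(select(asm$genes, "gene_id", "chromosome", "start", "end",
                       "strand", "rank"), by = "gene_id") |>
      left_join(select(oggs, "ogg_id", "category", "cluster", "subfamily"),
                by = "ogg_id"),
    membership = select(fam, "gene_id", "species", "ogg_id"),
    ogg_info = oggs |>
      mutate(presence = map_chr(.data$presence, paste, collapse = ",")),
    dup_mode = dup_truth,
    blocks = bind_rows(block_truth),
    pair_counts = seqs$pair_counts,
    motifs = motif_truth |> arrange(.data$gene_id, .data$start, .data$element),
    expression = expr$truth,
    violators = violators,
    retained_tx = asm$retained
  )

  ## ---- write files ------------------------------------------------------
  files <- list()
  wf <- function(name, path) { files[[name]] <<- path; path }
  for (sp in species) {
    sp_genes <- asm$genes |> filter(.data$species == sp)
    sp_feat <- asm$features |> filter(.data$gene_id %in% sp_genes$gene_id)
    write_gff3(sp_genes, sp_feat, wf(paste0("gff_", sp),
                                     file.path(out_dir, paste0(sp, "_annotation.gff3"))))
    write_fasta(asm$genomes[[sp]], wf(paste0("genome_", sp),
                                      file.path(out_dir, paste0(sp, "_genome.fa"))))
    ids <- c_sort(sp_genes$gene_id)
    cds_v <- all_cds_str[ids]
    write_fasta(cds_v, wf(paste0("cds_", sp),
                          file.path(out_dir, paste0(sp, "_cds.fa"))))
    prot_v <- vapply(cds_v, translate_cds, "")
    write_fasta(prot_v, wf(paste0("proteins_", sp),
                           file.path(out_dir, paste0(sp, "_proteins.fa"))))
    write_tsv_file(domains |> filter(.data$protein_id %in% ids),
                   wf(paste0("domains_", sp),
                      file.path(out_dir, paste0(sp, "_domains.tsv"))))
  }
  write_gff3(outg_genes_tb, outg_feat,
             wf("gff_outg", file.path(out_dir, "outg_annotation.gff3")))
  write_tsv_file(homology, wf("homology", file.path(out_dir, "homology.tsv")))
  write_tsv_file(outg_homology,
                 wf("outgroup_homology", file.path(out_dir, "outgroup_homology.tsv")))
  aln <- c(
    stats::setNames(vapply(seqs$member_cds[c_sort(names(seqs$member_cds))],
                           function(x) translate_cds(paste0(x, collapse = "")), ""),
                    c_sort(names(seqs$member_cds))),
    stats::setNames(vapply(seqs$refs, function(x) translate_cds(paste0(x, collapse = "")), ""),
                    names(seqs$refs))
  )
  write_fasta(aln, wf("alignment", file.path(out_dir, "protein_alignment.fa")))
  panel <- tibble(ref_id = names(seqs$refs), cluster = 1:14,
                  subfamily = subfamily_of_cluster(1:14))
  write_tsv_file(panel, wf("panel", file.path(out_dir, "reference_panel.tsv")))
  write_fasta(prom_seq, wf("promoters", file.path(out_dir, "promoters.fa")))
  write_tsv_file(lib, wf("motif_library", file.path(out_dir, "motif_library.tsv")))
  write_tsv_file(expr$counts, wf("expression", file.path(out_dir, "expression_counts.tsv")))
  write_tsv_file(qpcr, wf("qpcr", file.path(out_dir, "qpcr_ct.tsv")))
  for (nm in names(truth)) {
    write_tsv_file(truth[[nm]] |> select(-dplyr::any_of("presence_list")),
                   wf(paste0("truth_", nm), file.path(out_dir, "truth", paste0(nm, ".tsv"))))
  }
  invisible(structure(
    list(dir = out_dir, files = files, truth = truth, config = cfg,
         panel = panel, alignment = aln),
    class = "synth_dataset"
  ))
}
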