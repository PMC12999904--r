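# generate_dataset(): the full multi-species fixture builder. Internals are
# split into plan (orthogroups, duplication events, slot layout), sequence
# synthesis (hierarchical subfamily/cluster/member mutations with exact
# planted substitution counts), promoter planting, genome assembly, and
# expression/qPCR simulation. All randomness flows from stable sub-seeds of
# `config$seed`, one stream per section, so outputs are byte-identical
# across runs.

L_FAM <- 300L # family CDS length in codons; fixed so the family MSA is trivial

subfamily_of_cluster <- function(cl) {
  ifelse(cl <= 5, "MEKK", ifelse(cl <= 7, "ZIK", "RAF"))
}

random_dna <- function(n) paste0(sample(BASES, n, replace = TRUE), collapse = "")

# ---- planning ------------------------------------------------------------

plan_oggs <- function(cfg) {
  n <- cfg$n_oggs; N <- cfg$n_species
  n_c <- round(cfg$category_mix[[1]] * n)
  n_v <- round(cfg$category_mix[[2]] * n)
  n_r <- n - n_c - n_v
  if (n_r < 0) abort("category_mix rounds to more orthogroups than n_oggs.")
  if (n_r > 0 && N < 3) abort("Rare orthogroups need >= 3 species.")
  species <- sprintf("sp%02d", seq_len(N))
  cat_vec <- rep(c("conserved", "variable", "rare"), times = c(n_c, n_v, n_r))
  with_seed(sub_seed(cfg$seed, 1), {
    presence <- vector("list", n)
    for (i in seq_len(n)) {
      presence[[i]] <- switch(cat_vec[[i]],
        conserved = species,
        variable = species[-(((i - 1) %% N) + 1)],
        rare = {
          k <- if (N <= 3) 1L else sample(seq_len(N - 2), 1)
          c_sort(sample(species, k))
        }
      )
    }
    tibble(
      ogg_id = sprintf("OGG%03d", seq_len(n)),
      category = cat_vec,
      cluster = ((seq_len(n) - 1) %% 14) + 1,
      subfamily = subfamily_of_cluster(((seq_len(n) - 1) %% 14) + 1),
      home_chr = ((seq_len(n) - 1) %% cfg$chromosomes_per_species) + 1,
      omega_target = cfg$planted_omegas[((seq_len(n) - 1) %% length(cfg$planted_omegas)) + 1],
      presence = presence
    )
  })
}

plan_events <- function(cfg, oggs) {
  modes <- rep(names(cfg$dup_events), times = cfg$dup_events)
  E <- length(modes)
  if (E == 0) return(tibble(event = integer(0), mode = character(0),
                            species = character(0), ogg_id = character(0)))
  K <- cfg$chromosomes_per_species
  if (K < 2 && any(modes %in% c("WGD", "TRD", "DSD"))) {
    abort("WGD/TRD/DSD events need >= 2 chromosomes per species.")
  }
  conserved <- oggs$ogg_id[oggs$category == "conserved"]
  if (cfg$n_cross_blocks > 0) {
    # the last three conserved orthogroups are reserved for cross blocks
    conserved <- utils::head(conserved, -3)
  }
  if (length(conserved) < 1) abort("Duplication events need >= 1 free conserved orthogroup.")
  species <- sprintf("sp%02d", seq_len(cfg$n_species))
  ev <- tibble(
    event = seq_len(E),
    mode = modes,
    species = species[((seq_len(E) - 1) %% cfg$n_species) + 1],
    ogg_id = conserved[((seq_len(E) - 1) %% length(conserved)) + 1]
  )
  dup_key <- paste(ev$species, ev$ogg_id)
  if (anyDuplicated(dup_key)) {
    abort("Config too small: the same orthogroup would host two events in one species.")
  }
  ev
}

cross_block_oggs <- function(cfg, oggs, events) {
  if (cfg$n_cross_blocks == 0) return(character(0))
  if (cfg$n_species < 2 * cfg$n_cross_blocks) {
    abort("Need n_species >= 2 * n_cross_blocks.")
  }
  conserved <- oggs$ogg_id[oggs$category == "conserved"]
  if (length(conserved) < 3) abort("Cross blocks need >= 3 conserved orthogroups.")
  picked <- utils::tail(conserved, 3)
  # the block species must not host a duplication event on these orthogroups
  sp_pairs <- lapply(seq_len(cfg$n_cross_blocks), function(j) {
    sprintf("sp%02d", c(2 * j - 1, 2 * j))
  })
  clash <- events$ogg_id %in% picked &
    events$species %in% unlist(sp_pairs)
  if (any(clash)) abort("Config too small: cross-block orthogroups collide with events.")
  picked
}

# One species' slot layout. Returns the gene-id grid plus family placements.
layout_species <- function(cfg, sp, oggs, events, cross_oggs, seed) {
  K <- cfg$chromosomes_per_species; GPC <- cfg$genes_per_chromosome
  L <- cfg$block_length
  grid <- lapply(seq_len(K), function(ch) {
    sprintf("%s_bg_c%d_s%02d", sp, ch, seq_len(GPC))
  })
  win_cursor <- rep(1L, K)
  windows <- list() # registry rows
  alloc_window <- function(ch, kind, tag) {
    from <- win_cursor[[ch]]
    to <- from + L - 1L
    if (to > GPC) abort(sprintf(
      "genes_per_chromosome too small for windows on %s chr%d.", sp, ch))
    win_cursor[[ch]] <<- to + 1L
    windows[[length(windows) + 1]] <<- list(kind = kind, tag = tag, chr = ch,
                                            slots = from:to)
    length(windows)
  }
  fam <- list() # family placements: gene_id, ogg, role, chr, slot (slot NA until placed)
  placed_oggs <- character(0)
  add_fam <- function(gene_id, ogg_id, role, ch, slot) {
    fam[[length(fam) + 1]] <<- tibble(gene_id = gene_id, ogg_id = ogg_id,
                                      role = role, chr = ch, slot = slot)
  }
  mid <- ceiling(L / 2)
  ev_sp <- events[events$species == sp, , drop = FALSE]
  units <- list() # deferred placements: list(genes, offsets, chr)
  wgd_pairs <- character(0) # chromosome pairs carrying an intra-species block
  # a dispersed/transposed copy must not share a chromosome pair with a
  # planted intra-species block, or the chain DP could absorb its anchor
  safe_copy_chr <- function(from_chr) {
    for (cand in setdiff(seq_len(K), from_chr)) {
      key <- paste(min(from_chr, cand), max(from_chr, cand))
      if (!key %in% wgd_pairs) return(cand)
    }
    abort("No chromosome pair free of planted blocks for a copy placement.")
  }
  for (i in seq_len(nrow(ev_sp))) {
    e <- ev_sp[i, ]
    home <- oggs$home_chr[oggs$ogg_id == e$ogg_id]
    member <- sprintf("%s_%s", sp, e$ogg_id)
    copy <- sprintf("%s_%s_d1", sp, e$ogg_id)
    if (e$mode == "WGD") {
      chA <- ((e$event - 1) %% K) + 1
      chB <- (e$event %% K) + 1
      if (chB == chA) chB <- (chB %% K) + 1
      wa <- alloc_window(chA, "wgd_a", e$event)
      wb <- alloc_window(chB, "wgd_b", e$event)
      wgd_pairs <- c(wgd_pairs, paste(min(chA, chB), max(chA, chB)))
      add_fam(member, e$ogg_id, "member", chA, windows[[wa]]$slots[[mid]])
      add_fam(copy, e$ogg_id, "copy", chB, windows[[wb]]$slots[[mid]])
      placed_oggs <- c(placed_oggs, e$ogg_id)
    } else if (e$mode == "TRD") {
      chW <- ((e$event - 1) %% K) + 1
      chC <- safe_copy_chr(chW)
      w <- alloc_window(chW, "outgroup", e$event)
      add_fam(member, e$ogg_id, "member", chW, windows[[w]]$slots[[mid]])
      units[[length(units) + 1]] <- list(genes = copy, ogg = e$ogg_id,
                                         roles = "copy", offsets = 0L, chr = chC)
      placed_oggs <- c(placed_oggs, e$ogg_id)
    } else if (e$mode == "TD") {
      units[[length(units) + 1]] <- list(genes = c(member, copy), ogg = e$ogg_id,
                                         roles = c("member", "copy"),
                                         offsets = c(0L, 1L), chr = home)
      placed_oggs <- c(placed_oggs, e$ogg_id)
    } else if (e$mode == "PD") {
      units[[length(units) + 1]] <- list(genes = c(member, copy), ogg = e$ogg_id,
                                         roles = c("member", "copy"),
                                         offsets = c(0L, 3L), chr = home)
      placed_oggs <- c(placed_oggs, e$ogg_id)
    } else { # DSD
      chC <- safe_copy_chr(home)
      units[[length(units) + 1]] <- list(genes = member, ogg = e$ogg_id,
                                         roles = "member", offsets = 0L, chr = home)
      units[[length(units) + 1]] <- list(genes = copy, ogg = e$ogg_id,
                                         roles = "copy", offsets = 0L, chr = chC)
      placed_oggs <- c(placed_oggs, e$ogg_id)
    }
  }
  # cross-species blocks touching this species
  for (j in seq_len(cfg$n_cross_blocks)) {
    pair <- sprintf("sp%02d", c(2 * j - 1, 2 * j))
    if (!sp %in% pair) next
    ch <- ((j - 1) %% K) + 1
    w <- alloc_window(ch, "cross", j)
    offs <- unique(pmin(L, pmax(1, round(L * c(0.2, 0.5, 0.8)))))
    for (t in seq_along(cross_oggs)) {
      member <- sprintf("%s_%s", sp, cross_oggs[[t]])
      add_fam(member, cross_oggs[[t]], "member", ch, windows[[w]]$slots[[offs[[t]]]])
    }
    placed_oggs <- c(placed_oggs, cross_oggs)
  }
  # plain members
  present <- oggs[vapply(oggs$presence, function(p) sp %in% p, logical(1)), ,
                  drop = FALSE]
  plain <- present[!present$ogg_id %in% placed_oggs, , drop = FALSE]
  for (i in seq_len(nrow(plain))) {
    units[[length(units) + 1]] <- list(
      genes = sprintf("%s_%s", sp, plain$ogg_id[[i]]), ogg = plain$ogg_id[[i]],
      roles = "member", offsets = 0L, chr = plain$home_chr[[i]]
    )
  }
  # place units after the windows, shuffled, one background slot between units
  with_seed(seed, {
    for (ch in seq_len(K)) {
      here <- keep(units, function(u) u$chr == ch)
      if (length(here) == 0) next
      here <- here[sample.int(length(here))]
      cursor <- win_cursor[[ch]]
      for (u in here) {
        span <- max(u$offsets) + 1L
        if (cursor + span - 1L > GPC) {
          abort(sprintf("genes_per_chromosome too small on %s chr%d.", sp, ch))
        }
        for (t in seq_along(u$genes)) {
          add_fam(u$genes[[t]], u$ogg, u$roles[[t]], ch, cursor + u$offsets[[t]])
        }
        cursor <- cursor + span + 1L
      }
    }
  })
  fam_tb <- bind_rows(fam)
  if (anyDuplicated(paste(fam_tb$chr, fam_tb$slot))) {
    abort("Internal layout error: slot collision.")
  }
  for (i in seq_len(nrow(fam_tb))) {
    grid[[fam_tb$chr[[i]]]][[fam_tb$slot[[i]]]] <- fam_tb$gene_id[[i]]
  }
  list(grid = grid, fam = mutate(fam_tb, species = sp), windows = windows)
}
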