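## pipeline: end-to-end orchestration. genome_io -> orthology (focal pair
## plus each outgroup against the first focal species) -> presence/absence
## profiles -> Dollo parsimony -> per-loss features -> statistics ->
## putative gains with source filtering. All thresholds are surfaced in the
## run configuration with their conventional defaults.

#' Default pipeline options
#'
#' @return named list of thresholds: `evalue_max` 1e-10, `identity_min` 25,
#'   `flank_window` 45 aligned columns, `min_similarity` 0.5,
#'   `junction_min_reads` 1, `precision_window` 15, `gc_window` 100 bp,
#'   `resample_R` 10000, `seed` 1.
#' @export
pipeline_options <- function() {
  list(evalue_max = 1e-10, identity_min = 25, flank_window = 45,
       min_similarity = 0.5, junction_min_reads = 1,
       precision_window = 15, gc_window = 100, resample_R = 10000,
       seed = 1L)
}

#' Build a run configuration from a simulation output directory
#'
#' @param dir directory written by [simulate_clade()]/[write_simulation()].
#' @param ... overrides for [pipeline_options()] entries.
#' @return config list for [run_pipeline()].
#' @export
sim_run_config <- function(dir, ...) {
  sp_names <- c("DDB", "DPU", "PPA", "DFA", "EHI")
  species <- lapply(sp_names, function(sp) {
    list(fasta = file.path(dir, paste0(sp, ".fa")),
         gff3 = file.path(dir, paste0(sp, ".gff3")),
         junctions = file.path(dir, paste0(sp, ".junctions.bed")))
  })
  names(species) <- sp_names
  hits <- list()
  for (sp in setdiff(sp_names, "DDB")) {
    hits[[paste0("DDB_", sp)]] <- file.path(dir,
                                            paste0("hits_DDB_", sp, ".tsv"))
    hits[[paste0(sp, "_DDB")]] <- file.path(dir,
                                            paste0("hits_", sp, "_DDB.tsv"))
  }
  run_id <- NULL
  rid_path <- file.path(dir, "run_id.txt")
  if (file.exists(rid_path)) run_id <- readLines(rid_path)[1]
  gh <- file.path(dir, "gain_source_hits.tsv")
  gi <- file.path(dir, "gain_intron_info.tsv")
  cfg <- c(list(species = species, hits = hits,
                tree = "((((DDB,DPU),PPA),DFA),EHI);",
                focal = c("DDB", "DPU"), run_id = run_id,
                gain_hits = if (file.exists(gh)) gh else NULL,
                gain_intron_info = if (file.exists(gi)) gi else NULL),
           pipeline_options())
  opts <- list(...)
  cfg[names(opts)] <- opts
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys as in [sim_run_config()] output.
#' @return config list with [pipeline_options()] defaults filled in.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- yaml::read_yaml(path)
  defs <- pipeline_options()
  for (nm in names(defs)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defs[[nm]]
  cfg
}

validate_config <- function(config) {
  stopifnot(!is.null(config$species), length(config$focal) == 2)
  for (sp in names(config$species)) {
    s <- config$species[[sp]]
    if (is.null(s$models)) {
      for (f in c("fasta", "gff3")) {
        if (is.null(s[[f]]) || !file.exists(s[[f]])) {
          stop("missing ", f, " for species ", sp)
        }
      }
    }
  }
  invisible(TRUE)
}

## load per-species models/introns/junctions and hit tables; species
## entries may carry in-memory objects (models/introns/junctions from a
## simulation) instead of file paths
load_inputs <- function(config) {
  species <- list()
  for (sp in names(config$species)) {
    s <- config$species[[sp]]
    if (!is.null(s$models)) {
      introns <- s$introns
      if (!is.null(introns) && !"phase" %in% names(introns)) {
        introns$phase <- introns$cds_offset %% 3L
      }
      species[[sp]] <- list(models = s$models, introns = introns,
                            junctions = s$junctions)
    } else {
      genome <- read_genome_fasta(s$fasta)
      built <- build_gene_models(s$gff3, genome, species_id = sp)
      introns <- do.call(rbind, lapply(built$models, extract_introns,
                                       genome = genome))
      junctions <- NULL
      if (!is.null(s$junctions) && file.exists(s$junctions)) {
        junctions <- read_junctions_bed(s$junctions)
      }
      species[[sp]] <- list(models = built$models, introns = introns,
                            junctions = junctions, rejects = built$rejects)
    }
  }
  hits <- list()
  for (nm in names(config$hits)) {
    h <- config$hits[[nm]]
    hits[[nm]] <- if (is.character(h)) read_blast_tab(h) else h
  }
  list(species = species, hits = hits)
}

gene_introns <- function(inputs, sp, gene_id) {
  tab <- inputs$species[[sp]]$introns
  if (is.null(tab)) return(extract_introns(
    inputs$species[[sp]]$models[[gene_id]]))
  out <- tab[tab$gene_id == gene_id, , drop = FALSE]
  out[order(out$ordinal), , drop = FALSE]
}

#' Run the full intron loss/gain pipeline
#'
#' Sequences the stages: gene-model loading, reciprocal-best-hit
#' orthology, codon alignment and intron-site projection for the focal
#' pair, alignment-quality and junction filters, outgroup state
#' assignment, Dollo parsimony, loss-feature extraction, statistics, and
#' putative-gain calling with optional source filtering.
#'
#' @param config list (see [sim_run_config()], [read_run_config()]).
#' @return summary list with `counts`, `sites`, `profiles`, `losses`,
#'   `conserved_features`, `gains`, `stats`, `q1_similarity`, `run_id`,
#'   `seed`.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  inputs <- load_inputs(config)
  tree <- default_species_tree(config$tree)
  focal_a <- config$focal[1]
  focal_b <- config$focal[2]
  outgroups <- setdiff(tree$tip.label, config$focal)

  ## ---- orthologs -----------------------------------------------------
  pair_key <- function(a, b) paste0(a, "_", b)
  rbh <- function(a, b) {
    reciprocal_best_hits(inputs$hits[[pair_key(a, b)]],
                         inputs$hits[[pair_key(b, a)]],
                         evalue_max = config$evalue_max,
                         identity_min = config$identity_min)
  }
  orthologs <- rbh(focal_a, focal_b)
  out_maps <- lapply(outgroups, function(x) {
    m <- rbh(focal_a, x)
    stats::setNames(m$gene_b, m$gene_a)
  })
  names(out_maps) <- outgroups
  keep <- orthologs$gene_a %in% names(inputs$species[[focal_a]]$models) &
    orthologs$gene_b %in% names(inputs$species[[focal_b]]$models)
  orthologs <- orthologs[keep, , drop = FALSE]

  ## ---- focal-pair sites ----------------------------------------------
  aln_cache <- new.env(parent = emptyenv())
  get_alignment <- function(sp_x, gx, sp_y, gy) {
    key <- paste(gx, gy, sep = "|")
    if (!is.null(aln_cache[[key]])) return(aln_cache[[key]])
    a <- codon_alignment(inputs$species[[sp_x]]$models[[gx]],
                         inputs$species[[sp_y]]$models[[gy]])
    aln_cache[[key]] <- a
    a
  }
  outgroup_sites <- new.env(parent = emptyenv())  # (col,phase) per pair

  all_sites <- list()
  aln_sims <- numeric(0)
  for (i in seq_len(nrow(orthologs))) {
    ga <- orthologs$gene_a[i]
    gb <- orthologs$gene_b[i]
    aln <- get_alignment(focal_a, ga, focal_b, gb)
    aln_sims[i] <- alignment_similarity(aln)
    ia <- gene_introns(inputs, focal_a, ga)
    ib <- gene_introns(inputs, focal_b, gb)
    sites <- project_intron_sites(aln, ia, ib)
    if (nrow(sites) == 0L) next
    fs <- t(vapply(sites$column, function(col)
      flank_similarity(aln, col, config$flank_window), numeric(2)))
    sites$sim_left <- fs[, 1]
    sites$sim_right <- fs[, 2]
    all_sites[[length(all_sites) + 1L]] <- sites
  }
  if (length(all_sites) == 0L) {
    stop("no intron sites found in any ortholog pair")
  }
  sites <- do.call(rbind, all_sites)
  sites <- filter_sites(sites, min_similarity = config$min_similarity,
                        alignment_similarities = aln_sims)
  q1 <- attr(sites, "q1")
  sites <- junction_filter(sites,
                           junctions_a = inputs$species[[focal_a]]$junctions,
                           junctions_b = inputs$species[[focal_b]]$junctions,
                           min_reads = config$junction_min_reads)
  sites$site_id <- sprintf("%s|%d|%d", sites$gene_a, sites$column,
                           sites$phase)
  ## focal-A coordinate of every site (also for sites absent in A)
  sites$offset_a_coord <- sites$offset_a
  need <- is.na(sites$offset_a_coord)
  if (any(need)) {
    for (i in which(need)) {
      aln <- get_alignment(focal_a, sites$gene_a[i], focal_b,
                           sites$gene_b[i])
      sites$offset_a_coord[i] <- column_to_offset_aln(aln, "a",
                                                      sites$column[i])
    }
  }

  ## ---- outgroup states and profiles ----------------------------------
  retained <- sites[sites$status %in% c("conserved", "discordant_a_only",
                                        "discordant_b_only"), ,
                    drop = FALSE]
  out_state <- function(x, ga, offset, phase) {
    gx <- out_maps[[x]][ga]
    if (is.na(gx) || !gx %in% names(inputs$species[[x]]$models)) {
      return("unknown")
    }
    aln <- get_alignment(focal_a, ga, x, gx)
    skey <- paste(ga, gx, sep = "|")
    if (is.null(outgroup_sites[[skey]])) {
      ix <- gene_introns(inputs, x, gx)
      keys <- character(0)
      if (nrow(ix) > 0L) {
        cols <- vapply(ix$cds_offset, function(o)
          offset_to_column_aln(aln, "b", o), numeric(1))
        keys <- paste(cols, ix$phase)
      }
      outgroup_sites[[skey]] <- keys
    }
    col <- tryCatch(offset_to_column_aln(aln, "a", offset),
                    error = function(e) NA)
    if (is.na(col)) return("unknown")
    fs <- flank_similarity(aln, col, config$flank_window)
    if (any(is.na(fs)) || any(fs < config$min_similarity)) {
      return("unknown")
    }
    if (paste(col, phase) %in% outgroup_sites[[skey]]) "present" else
      "absent"
  }
  prof_rows <- list()
  for (i in seq_len(nrow(retained))) {
    r <- retained[i, ]
    row <- list(site_id = r$site_id)
    row[[focal_a]] <- if (r$status %in% c("conserved",
                                          "discordant_a_only"))
      "present" else "absent"
    row[[focal_b]] <- if (r$status %in% c("conserved",
                                          "discordant_b_only"))
      "present" else "absent"
    for (x in outgroups) {
      row[[x]] <- out_state(x, r$gene_a, r$offset_a_coord, r$phase)
    }
    prof_rows[[i]] <- as.data.frame(row)
  }
  profiles <- do.call(rbind, prof_rows)

  ## ---- Dollo events ---------------------------------------------------
  losses_raw <- loss_calls(profiles, tree, focal = config$focal)
  gains_raw <- putative_gain_calls(profiles, tree)
  gains_raw <- gains_raw[gains_raw$species %in% config$focal, ,
                         drop = FALSE]
  ## a terminal "loss" on a focal branch at a single-presence site is the
  ## flip side of a putative gain in the other species; Dollo with strict
  ## outgroup confirmation assigns each site to exactly one category
  losses_raw <- losses_raw[!losses_raw$site_id %in% gains_raw$site_id, ,
                           drop = FALSE]

  ## ---- loss features --------------------------------------------------
  site_by_id <- retained[match(losses_raw$site_id, retained$site_id), ,
                         drop = FALSE]
  loss_feats <- list()
  conserved_gc_cache <- new.env(parent = emptyenv())
  conserved_gc_for_gene <- function(sp, gene_id, pair_sites, side) {
    key <- paste(sp, gene_id)
    if (!is.null(conserved_gc_cache[[key]])) {
      return(conserved_gc_cache[[key]])
    }
    cds <- inputs$species[[sp]]$models[[gene_id]]$spliced_cds
    offs <- pair_sites[pair_sites$status == "conserved",
                       paste0("offset_", side)]
    gcs <- vapply(offs, function(o)
      flank_gc(cds, o, config$gc_window)$gc, numeric(1))
    conserved_gc_cache[[key]] <- gcs
    gcs
  }
  for (i in seq_len(nrow(losses_raw))) {
    r <- site_by_id[i, ]
    sp_lost <- losses_raw$species[i]
    lost_in_a <- sp_lost == focal_a
    sp_keep <- if (lost_in_a) focal_b else focal_a
    keep_gene <- if (lost_in_a) r$gene_b else r$gene_a
    lost_gene <- if (lost_in_a) r$gene_a else r$gene_b
    keep_off <- if (lost_in_a) r$offset_b else r$offset_a
    keep_ord <- if (lost_in_a) r$ordinal_b else r$ordinal_a
    aln <- get_alignment(focal_a, r$gene_a, focal_b, r$gene_b)
    prec <- classify_precision(aln, r$column, config$precision_window)
    keep_cds <- inputs$species[[sp_keep]]$models[[keep_gene]]$spliced_cds
    keep_intr <- gene_introns(inputs, sp_keep, keep_gene)
    keep_intr <- keep_intr[keep_intr$ordinal == keep_ord, , drop = FALSE]
    intron_seq <- keep_intr$sequence[1]
    up <- substr_clip(keep_cds, keep_off - 20L, keep_off)
    down <- substr_clip(keep_cds, keep_off + 1L, keep_off + 20L)
    reps <- if (!is.na(intron_seq)) {
      direct_repeat_length(up, intron_seq, down)
    } else c(repeat_len_5p = NA_integer_, repeat_len_3p = NA_integer_)
    ## flank GC in the genome that lost the intron; the lost-side CDS
    ## coordinate is derived from the alignment column
    lost_cds <- inputs$species[[sp_lost]]$models[[lost_gene]]$spliced_cds
    lost_off <- if (lost_in_a) r$offset_a_coord else
      column_to_offset_aln(aln, "b", r$column)
    gc <- flank_gc(lost_cds, lost_off, config$gc_window)
    pair_sites <- sites[sites$gene_a == r$gene_a, , drop = FALSE]
    cons_gc <- conserved_gc_for_gene(sp_lost, lost_gene, pair_sites,
                                     if (lost_in_a) "a" else "b")
    loss_feats[[i]] <- data.frame(
      loss_id = sprintf("loss|%s|%s", sp_lost, r$site_id),
      site_id = r$site_id, species = sp_lost, gene = lost_gene,
      partner_gene = keep_gene, ordinal = keep_ord,
      partner_offset = keep_off, focal_offset = lost_off,
      precise = prec$precise, flank_indel_bp = prec$flank_indel_bp,
      relative_position = relative_intron_position(keep_off,
                                                   nchar(keep_cds)),
      intron_length = keep_intr$length[1],
      repeat_len_5p = reps[["repeat_len_5p"]],
      repeat_len_3p = reps[["repeat_len_3p"]],
      flank_gc = gc$gc,
      relative_gc = relative_flank_gc(gc$gc, cons_gc),
      fourfold_gc = fourfold_gc(lost_cds, lost_off, config$gc_window))
  }
  losses <- if (length(loss_feats)) do.call(rbind, loss_feats) else
    data.frame(loss_id = character(), site_id = character(),
               species = character(), gene = character(),
               partner_gene = character(), ordinal = integer(),
               partner_offset = integer(), focal_offset = integer(),
               precise = logical(), flank_indel_bp = integer(),
               relative_position = numeric(), intron_length = integer(),
               repeat_len_5p = integer(), repeat_len_3p = integer(),
               flank_gc = numeric(), relative_gc = numeric(),
               fourfold_gc = numeric())

  ## ---- conserved-site features per focal species ----------------------
  cons <- sites[sites$status == "conserved", , drop = FALSE]
  cons_feats <- list()
  for (sp in config$focal) {
    side <- if (sp == focal_a) "a" else "b"
    gene_col <- paste0("gene_", side)
    off_col <- paste0("offset_", side)
    ord_col <- paste0("ordinal_", side)
    for (i in seq_len(nrow(cons))) {
      gid <- cons[[gene_col]][i]
      cds <- inputs$species[[sp]]$models[[gid]]$spliced_cds
      off <- cons[[off_col]][i]
      itab <- gene_introns(inputs, sp, gid)
      itab <- itab[itab$ordinal == cons[[ord_col]][i], , drop = FALSE]
      up <- substr_clip(cds, off - 20L, off)
      down <- substr_clip(cds, off + 1L, off + 20L)
      reps <- if (nrow(itab) == 1L && !is.na(itab$sequence[1])) {
        direct_repeat_length(up, itab$sequence[1], down)
      } else c(repeat_len_5p = NA_integer_, repeat_len_3p = NA_integer_)
      cons_feats[[length(cons_feats) + 1L]] <- data.frame(
        site_id = cons$site_id[i], species = sp, gene = gid,
        ordinal = cons[[ord_col]][i],
        relative_position = relative_intron_position(off, nchar(cds)),
        intron_length = itab$length[1],
        flank_gc = flank_gc(cds, off, config$gc_window)$gc,
        repeat_len_5p = reps[["repeat_len_5p"]],
        repeat_len_3p = reps[["repeat_len_3p"]])
    }
  }
  conserved_features <- if (length(cons_feats))
    do.call(rbind, cons_feats) else NULL

  ## ---- statistics ------------------------------------------------------
  stats_out <- list()
  for (sp in config$focal) {
    sl <- losses[losses$species == sp, , drop = FALSE]
    sc <- conserved_features[conserved_features$species == sp, ,
                             drop = FALSE]
    res <- list(n_losses = nrow(sl),
                n_precise = sum(sl$precise),
                n_imprecise = sum(!sl$precise))
    if (nrow(sl) >= 2L && !is.null(sc) && nrow(sc) >= 2L) {
      res$position_test <- mann_whitney_u(sl$relative_position,
                                          sc$relative_position)
      res$gc_test <- mann_whitney_u(sl$flank_gc, sc$flank_gc)
      res$length_test <- mann_whitney_u(sl$intron_length,
                                        sc$intron_length)
      res$median_lost_position <- stats::median(sl$relative_position)
      res$median_conserved_position <- stats::median(sc$relative_position)
      res$median_lost_gc <- stats::median(sl$flank_gc)
      res$median_conserved_gc <- stats::median(sc$flank_gc)
    }
    ## pre-loss gene structures: extant introns + lost sites, ordered by
    ## focal-species coordinate
    adj <- preloss_structures(sp, sl, inputs, config, focal_a)
    res$observed_adjacent_pairs <- adjacent_loss_pairs(adj$lost)
    if (nrow(adj$lost) > 0L && nrow(adj$pool) > nrow(adj$lost)) {
      res$resampling <- resample_adjacent_pairs(
        adj$pool, n_lost = nrow(adj$lost),
        observed = res$observed_adjacent_pairs,
        R = config$resample_R, seed = config$seed)
      res$resampling$replicates <- NULL
      nul <- adjacency_null_distribution(
        adj$genes, observed = res$observed_adjacent_pairs)
      res$independence_p <- nul$p_tail
    }
    ext <- inputs$species[[sp]]$introns
    if (!is.null(ext) && nrow(ext) >= 2L) {
      ext_pos <- position_of_extant(sp, inputs)
      res$extant_position_bias <- wilcoxon_signed_rank(ext_pos,
                                                       alternative = "less")
    }
    stats_out[[sp]] <- res
  }
  n_ext_a <- nrow(inputs$species[[focal_a]]$introns)
  n_ext_b <- nrow(inputs$species[[focal_b]]$introns)
  stats_out$loss_rate_chi2 <- chi_square_2x2(
    stats_out[[focal_a]]$n_losses, n_ext_a,
    stats_out[[focal_b]]$n_losses, n_ext_b)

  ## ---- gains ------------------------------------------------------------
  gain_rows <- list()
  for (i in seq_len(nrow(gains_raw))) {
    r <- retained[match(gains_raw$site_id[i], retained$site_id), ]
    sp <- gains_raw$species[i]
    in_a <- sp == focal_a
    gid <- if (in_a) r$gene_a else r$gene_b
    ord <- if (in_a) r$ordinal_a else r$ordinal_b
    off <- if (in_a) r$offset_a else r$offset_b
    itab <- gene_introns(inputs, sp, gid)
    itab <- itab[itab$ordinal == ord, , drop = FALSE]
    gain_rows[[i]] <- data.frame(
      site_id = gains_raw$site_id[i], species = sp, gene = gid,
      ordinal = ord, cds_offset = off,
      intron_id = sprintf("%s:gain%d", gid, ord),
      length = itab$length[1],
      canonical_boundaries = if (!is.na(itab$sequence[1]))
        splice_boundary_check(itab$sequence[1]) else NA)
  }
  gains <- if (length(gain_rows)) do.call(rbind, gain_rows) else
    data.frame(site_id = character(), species = character(),
               gene = character(), ordinal = integer(),
               cds_offset = integer(), intron_id = character(),
               length = integer(), canonical_boundaries = logical())
  source_report <- NULL
  if (!is.null(config$gain_hits) && nrow(gains) > 0L) {
    gh <- config$gain_hits
    if (is.character(gh)) gh <- read_blast_tab(gh)
    gi <- config$gain_intron_info
    if (is.character(gi)) {
      gi <- utils::read.table(gi, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    }
    gh <- gh[gh$query_id %in% gi$intron_id, , drop = FALSE]
    source_report <- filter_source_hits(gh, gi,
                                        evalue_max = config$evalue_max)
  }

  counts <- list(
    n_ortholog_pairs = nrow(orthologs),
    n_sites = nrow(sites),
    n_conserved = sum(sites$status == "conserved"),
    n_discordant = sum(sites$status %in% c("discordant_a_only",
                                           "discordant_b_only")),
    n_discarded_low_quality = sum(sites$status == "discarded_low_quality"),
    n_discarded_junction = sum(sites$status == "discarded_junction"),
    n_gains = stats::setNames(
      vapply(config$focal, function(sp) sum(gains$species == sp),
             numeric(1)), config$focal))

  list(counts = counts, sites = sites, profiles = profiles,
       losses = losses, conserved_features = conserved_features,
       gains = gains, gain_source_report = source_report,
       stats = stats_out, q1_similarity = q1,
       run_id = config$run_id, seed = config$seed,
       focal = config$focal)
}

## reconstruct per-gene pre-loss intron structures for one focal species:
## extant introns plus sites lost on that branch, ordered by the species'
## own CDS coordinate; ordinals are ranks in that ordering
preloss_structures <- function(sp, sp_losses, inputs, config, focal_a) {
  ext <- inputs$species[[sp]]$introns
  lost_off <- if (nrow(sp_losses) > 0L) data.frame(
    gene_id = sp_losses$gene, offset = sp_losses$focal_offset,
    lost = TRUE) else
      data.frame(gene_id = character(), offset = integer(),
                 lost = logical())
  ext_off <- if (!is.null(ext) && nrow(ext) > 0L) data.frame(
    gene_id = ext$gene_id, offset = ext$cds_offset, lost = FALSE) else
      data.frame(gene_id = character(), offset = integer(),
                 lost = logical())
  all <- rbind(lost_off, ext_off)
  if (nrow(all) == 0L) {
    z <- data.frame(gene_id = character(), ordinal = integer())
    return(list(lost = z, pool = z,
                genes = data.frame(n_introns = integer(),
                                   k_lost = integer())))
  }
  all <- all[order(all$gene_id, all$offset), , drop = FALSE]
  all$ordinal <- stats::ave(all$offset, all$gene_id,
                            FUN = seq_along)
  genes <- do.call(rbind, lapply(split(all, all$gene_id), function(d) {
    data.frame(n_introns = nrow(d), k_lost = sum(d$lost))
  }))
  genes <- genes[genes$k_lost > 0L, , drop = FALSE]
  list(lost = all[all$lost, c("gene_id", "ordinal")],
       pool = all[, c("gene_id", "ordinal")],
       genes = genes)
}

position_of_extant <- function(sp, inputs) {
  ext <- inputs$species[[sp]]$introns
  lens <- vapply(ext$gene_id, function(g)
    nchar(inputs$species[[sp]]$models[[g]]$spliced_cds), numeric(1))
  ext$cds_offset / lens
}

#' Render a pipeline summary as text and JSON
#'
#' @param summary result of [run_pipeline()].
#' @param out_dir optional directory; when given, writes `summary.json`,
#'   `report.txt` and the site/loss/gain tables as TSV.
#' @return character vector of report lines, invisibly when writing.
#' @export
report <- function(summary, out_dir = NULL) {
  fmt_p <- function(p) formatC(p, format = "g", digits = 4)
  lines <- c(
    sprintf("intronevo %s  (seed %s, run %s)",
            as.character(utils::packageVersion("intronevo")),
            summary$seed, ifelse(is.null(summary$run_id), "-",
                                 summary$run_id)),
    sprintf("ortholog pairs: %d", summary$counts$n_ortholog_pairs),
    sprintf("intron sites: %d (%d conserved, %d discordant, %d low-quality, %d junction-discarded)",
            summary$counts$n_sites, summary$counts$n_conserved,
            summary$counts$n_discordant,
            summary$counts$n_discarded_low_quality,
            summary$counts$n_discarded_junction))
  for (sp in summary$focal) {
    s <- summary$stats[[sp]]
    lines <- c(lines, sprintf(
      "%s: %d losses (%d precise, %d imprecise), %d putative gains",
      sp, s$n_losses, s$n_precise, s$n_imprecise,
      summary$counts$n_gains[[sp]]))
    if (!is.null(s$position_test)) {
      lines <- c(lines, sprintf(
        "  position lost vs conserved: median %.3f vs %.3f (MWU p=%s)",
        s$median_lost_position, s$median_conserved_position,
        fmt_p(s$position_test$p)))
      lines <- c(lines, sprintf(
        "  flank GC lost vs conserved: median %.3f vs %.3f (MWU p=%s)",
        s$median_lost_gc, s$median_conserved_gc, fmt_p(s$gc_test$p)))
    }
    lines <- c(lines, sprintf("  adjacent-loss pairs: %d",
                              s$observed_adjacent_pairs))
    if (!is.null(s$resampling)) {
      lines <- c(lines, sprintf(
        "  resampling p=%s (R=%d, seed %d); independence-null p=%s",
        fmt_p(s$resampling$p_value), s$resampling$R, s$resampling$seed,
        fmt_p(s$independence_p)))
    }
  }
  lr <- summary$stats$loss_rate_chi2
  lines <- c(lines, sprintf("loss-rate chi-square: chi2=%.3f p=%s",
                            lr$chi2, fmt_p(lr$p)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(lines, file.path(out_dir, "report.txt"))
    jsonlite::write_json(
      list(counts = summary$counts, stats = summary$stats,
           seed = summary$seed, run_id = summary$run_id,
           version = as.character(utils::packageVersion("intronevo"))),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
    write_tsv(summary$sites, file.path(out_dir, "sites.tsv"))
    write_tsv(summary$losses, file.path(out_dir, "losses.tsv"))
    write_tsv(summary$gains, file.path(out_dir, "gains.tsv"))
    return(invisible(lines))
  }
  lines
}

#' Compare pipeline calls against simulation ground truth
#'
#' Maps each pipeline loss call back to its ancestral intron via the
#' simulator's per-species intron bookkeeping and scores recovery.
#'
#' @param summary result of [run_pipeline()] on a simulated dataset; its
#'   `run_id` must match the truth's.
#' @param truth `truth` element of a [simulate_clade()] result.
#' @return list: `loss_sensitivity` (overall and per mechanism),
#'   `loss_call_precision`, `classification_accuracy` (precise/imprecise),
#'   `gain_sensitivity`, `gain_precision`, `planted_adjacent_pairs`,
#'   `detected_adjacent_pairs`, `matches` (per-call table).
#' @export
truth_compare <- function(summary, truth) {
  if (is.null(summary$run_id) || summary$run_id != truth$run_id) {
    stop("run id mismatch between pipeline summary and truth (",
         ifelse(is.null(summary$run_id), "none", summary$run_id), " vs ",
         truth$run_id, ")")
  }
  ev <- truth$events
  si <- truth$species_introns
  losses <- summary$losses
  tl <- ev[ev$type == "loss", , drop = FALSE]

  match_rows <- list()
  for (i in seq_len(nrow(losses))) {
    pg <- losses$partner_gene[i]
    po <- losses$ordinal[i]
    anc <- si$anc_ordinal[si$gene_id == pg & si$ordinal == po]
    gidx <- si$gene_index[si$gene_id == pg & si$ordinal == po]
    matched <- FALSE
    mech <- NA_character_
    true_precise <- NA
    if (length(anc) == 1L && anc > 0L) {
      hit <- which(tl$species == losses$species[i] &
                     tl$gene_index == gidx & tl$anc_ordinal == anc)
      if (length(hit) == 1L) {
        matched <- TRUE
        mech <- tl$mechanism[hit]
        true_precise <- tl$precise[hit]
      }
    }
    match_rows[[i]] <- data.frame(
      loss_id = losses$loss_id[i], species = losses$species[i],
      matched = matched, mechanism = mech,
      called_precise = losses$precise[i], true_precise = true_precise)
  }
  matches <- if (length(match_rows)) do.call(rbind, match_rows) else
    data.frame(loss_id = character(), species = character(),
               matched = logical(), mechanism = character(),
               called_precise = logical(), true_precise = logical())

  sens_overall <- if (nrow(tl) > 0L) sum(matches$matched) / nrow(tl) else
    NA_real_
  sens_mech <- vapply(unique(tl$mechanism), function(m) {
    n <- sum(tl$mechanism == m)
    if (n == 0L) return(NA_real_)
    sum(matches$mechanism == m, na.rm = TRUE) / n
  }, numeric(1))
  call_precision <- if (nrow(matches) > 0L)
    mean(matches$matched) else NA_real_
  cls <- matches[matches$matched, , drop = FALSE]
  cls_acc <- if (nrow(cls) > 0L)
    mean(cls$called_precise == cls$true_precise) else NA_real_

  tg <- ev[ev$type == "gain", , drop = FALSE]
  gains <- summary$gains
  gmatched <- 0L
  for (i in seq_len(nrow(gains))) {
    anc <- si$anc_ordinal[si$gene_id == gains$gene[i] &
                            si$ordinal == gains$ordinal[i]]
    gidx <- si$gene_index[si$gene_id == gains$gene[i] &
                            si$ordinal == gains$ordinal[i]]
    if (length(anc) == 1L && anc < 0L &&
        any(tg$species == gains$species[i] & tg$gene_index == gidx &
              tg$focal_offset == gains$cds_offset[i])) {
      gmatched <- gmatched + 1L
    }
  }

  planted_pairs <- vapply(unique(tl$species), function(sp) {
    d <- tl[tl$species == sp, , drop = FALSE]
    adjacent_loss_pairs(data.frame(gene_id = d$gene_index,
                                   ordinal = d$anc_ordinal))
  }, integer(1))
  detected_pairs <- vapply(summary$focal, function(sp)
    summary$stats[[sp]]$observed_adjacent_pairs, integer(1))

  list(loss_sensitivity = sens_overall,
       loss_sensitivity_by_mechanism = sens_mech,
       loss_call_precision = call_precision,
       classification_accuracy = cls_acc,
       gain_sensitivity = if (nrow(tg) > 0L) gmatched / nrow(tg) else
         NA_real_,
       gain_precision = if (nrow(gains) > 0L) gmatched / nrow(gains) else
         NA_real_,
       planted_adjacent_pairs = planted_pairs,
       detected_adjacent_pairs = detected_pairs,
       matches = matches)
}
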