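## synthetic_data: a five-species toy clade with known intron histories.
## Ancestral multi-exon genes are built once, then each focal terminal
## branch applies a configurable number of intron losses under a mix of
## mechanisms:
##   reverse_transcription - a (possibly partial, 3'-anchored) cDNA
##     recombines with the genome, removing one intron or a 3' run of
##     adjacent introns precisely, optionally elevating flank GC (biased
##     gene conversion);
##   genomic_deletion - the intron plus a small multiple-of-three exonic
##     indel is removed (imprecise loss; frame preserved);
##   nhej - a short direct repeat is planted at the intron boundary in the
##     ancestor, then the intron is removed precisely.
## Occasional gains copy a recorded donor segment and wrap it in GT..AG.
## Every event is recorded in a ground-truth table for recovery tests.

#' Simulation configuration with defaults
#'
#' @param seed RNG seed; the whole simulation is a deterministic function
#'   of the config.
#' @param n_genes number of ancestral gene families.
#' @param introns_per_gene integer range (min, max), uniform.
#' @param intron_len_meanlog,intron_len_sdlog log-normal intron length
#'   (defaults give median 100 bp).
#' @param base_gc,gene_gc_sd exonic GC level and per-gene heterogeneity.
#' @param loss_counts named integer vector: intron losses per focal
#'   terminal branch.
#' @param mechanism_mix named fractions over
#'   `reverse_transcription`/`genomic_deletion`/`nhej`; must sum to 1.
#' @param rt_3prime_bias probability that an RT loss uses a partial
#'   (3'-anchored) cDNA rather than a full-length one; 0 = no positional
#'   bias.
#' @param partial_cdna_scale mean partial-cDNA length (bp, exponential).
#' @param rt_coloss_prob probability an RT recombination removes the whole
#'   run of introns covered by the cDNA rather than a single one.
#' @param gc_elevation_at_loss additive GC shift planted in +/-100 bp exon
#'   flanks of RT-loss sites (0 disables).
#' @param gain_counts named integer vector: intron gains per focal species.
#' @param subst_rate per-site substitution probability on the focal
#'   terminal branches; outgroups use fixed multipliers (PPA x2, DFA x3,
#'   EHI x5).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 60L,
                       introns_per_gene = c(1L, 12L),
                       intron_len_meanlog = log(100),
                       intron_len_sdlog = 0.4,
                       base_gc = 0.35, gene_gc_sd = 0.05,
                       loss_counts = c(DDB = 20L, DPU = 10L),
                       mechanism_mix = c(reverse_transcription = 1,
                                         genomic_deletion = 0, nhej = 0),
                       rt_3prime_bias = 0.8, partial_cdna_scale = 500,
                       rt_coloss_prob = 0.25,
                       gc_elevation_at_loss = 0,
                       gain_counts = c(DDB = 2L, DPU = 2L),
                       subst_rate = 0.01) {
  stopifnot(abs(sum(mechanism_mix) - 1) < 1e-9,
            all(mechanism_mix >= 0), subst_rate >= 0,
            rt_3prime_bias >= 0, rt_3prime_bias <= 1,
            setequal(names(mechanism_mix),
                     c("reverse_transcription", "genomic_deletion",
                       "nhej")))
  structure(list(
    seed = seed, n_genes = n_genes, introns_per_gene = introns_per_gene,
    intron_len_meanlog = intron_len_meanlog,
    intron_len_sdlog = intron_len_sdlog,
    base_gc = base_gc, gene_gc_sd = gene_gc_sd,
    loss_counts = loss_counts, mechanism_mix = mechanism_mix,
    rt_3prime_bias = rt_3prime_bias,
    partial_cdna_scale = partial_cdna_scale,
    rt_coloss_prob = rt_coloss_prob,
    gc_elevation_at_loss = gc_elevation_at_loss,
    gain_counts = gain_counts, subst_rate = subst_rate
  ), class = "sim_config")
}

SIM_SPECIES <- c("DDB", "DPU", "PPA", "DFA", "EHI")
SIM_SUBST_MULT <- c(DDB = 1, DPU = 1, PPA = 2, DFA = 3, EHI = 5)

rand_dna <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

## patch in-frame stop codons (third base -> T) in a char vector of exons
fix_stops <- function(exons) {
  spliced <- paste(exons, collapse = "")
  n <- nchar(spliced)
  if (n >= 3L) {
    starts <- seq.int(1L, n - 2L, by = 3L)
    codons <- substring(spliced, starts, starts + 2L)
    bad <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (length(bad) > 0L) {
      spl <- strsplit(spliced, "", fixed = TRUE)[[1]]
      spl[starts[bad] + 2L] <- "T"
      spliced <- paste(spl, collapse = "")
    }
  }
  lens <- nchar(exons)
  ends <- cumsum(lens)
  substring(spliced, ends - lens + 1L, ends)
}

## apply substitutions to a string; stop codons cleaned later
substitute_bases <- function(seq, rate, protect_head = 0L,
                             protect_tail = 0L) {
  n <- nchar(seq)
  lo <- protect_head + 1L
  hi <- n - protect_tail
  if (rate <= 0 || hi < lo) return(seq)
  k <- stats::rbinom(1L, hi - lo + 1L, rate)
  if (k == 0L) return(seq)
  pos <- sample(lo:hi, k)
  spl <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) {
    spl[p] <- sample(setdiff(c("A", "C", "G", "T"), spl[p]), 1L)
  }
  paste(spl, collapse = "")
}

## raise GC of a window by flipping ~delta*width A/T bases to G/C
elevate_gc <- function(exon, center, delta, window = 100L) {
  if (delta <= 0) return(exon)
  lo <- max(1L, center - window + 1L)
  hi <- min(nchar(exon), center + window)
  if (hi < lo) return(exon)
  spl <- strsplit(exon, "", fixed = TRUE)[[1]]
  at <- which(spl[lo:hi] %in% c("A", "T")) + lo - 1L
  k <- min(length(at), round(delta * (hi - lo + 1L)))
  if (k > 0L) {
    flip <- if (length(at) == 1L) at else sample(at, k)
    spl[flip] <- sample(c("G", "C"), length(flip), replace = TRUE)
  }
  paste(spl, collapse = "")
}

## current cds offsets of a species gene (introns live between exons)
gene_offsets <- function(g) {
  if (length(g$introns) == 0L) return(integer(0))
  cumsum(nchar(g$exons))[seq_along(g$introns)]
}

#' Simulate a five-species clade with recorded intron histories
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, writes per-species FASTA
#'   and GFF3, junction BED, reciprocal hit tables (DDB vs each other
#'   species, both directions), gain-source hit tables and the ground-truth
#'   TSVs, all consumable by [run_pipeline()].
#' @return list with `species` (per species: `genome` DNAStringSet,
#'   `models` list of `gene_model`, `introns` data.frame, `junctions`
#'   data.frame), `hits` (named list of hit tables), `gain_hits`,
#'   `gain_intron_info`, `truth` (list `events`, `ancestral_introns`,
#'   `run_id`), and `config`.
#' @export
simulate_clade <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_clade_impl(config, out_dir))
}

simulate_clade_impl <- function(cfg, out_dir) {
  n_genes <- cfg$n_genes

  ## ---- ancestral gene families -------------------------------------
  anc <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    n_int <- sample(seq(cfg$introns_per_gene[1], cfg$introns_per_gene[2]),
                    1L)
    ex_len <- sample(90:240, n_int + 1L, replace = TRUE)
    pad <- (3L - sum(ex_len) %% 3L) %% 3L
    ex_len[n_int + 1L] <- ex_len[n_int + 1L] + pad
    p_gc <- min(0.8, max(0.1, stats::rnorm(1L, cfg$base_gc,
                                           cfg$gene_gc_sd)))
    exons <- vapply(ex_len, rand_dna, character(1), gc = p_gc)
    exons <- fix_stops(exons)
    introns <- vapply(seq_len(n_int), function(i) {
      len <- max(10L, round(stats::rlnorm(1L, cfg$intron_len_meanlog,
                                          cfg$intron_len_sdlog)))
      paste0("GT", rand_dna(len - 4L, 0.2), "AG")
    }, character(1))
    anc[[g]] <- list(exons = exons, introns = introns,
                     anc_ord = seq_len(n_int),
                     strand = sample(c("+", "-"), 1L, prob = c(0.8, 0.2)),
                     gc = p_gc)
  }
  anc_introns <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
    n_int <- length(anc[[g]]$introns)
    if (n_int == 0L) return(NULL)
    data.frame(gene_index = g, ordinal = seq_len(n_int),
               cds_offset = cumsum(nchar(anc[[g]]$exons))[seq_len(n_int)],
               length = nchar(anc[[g]]$introns))
  }))

  total_introns <- nrow(anc_introns)
  if (any(cfg$loss_counts > total_introns)) {
    stop("more losses requested than available introns (",
         total_introns, ")")
  }

  ## ---- plan events per focal branch --------------------------------
  mech_plan <- list()
  for (sp in names(cfg$loss_counts)) {
    budget <- cfg$loss_counts[[sp]]
    raw <- cfg$mechanism_mix * budget
    n_mech <- floor(raw)
    rem <- budget - sum(n_mech)
    if (rem > 0L) {
      o <- order(raw - n_mech, decreasing = TRUE)
      n_mech[o[seq_len(rem)]] <- n_mech[o[seq_len(rem)]] + 1L
    }
    mech_plan[[sp]] <- n_mech
  }

  ## NHEJ targets: planted in the ancestor so the repeat is inherited by
  ## every species, including the one that keeps the intron
  nhej_targets <- list()
  for (sp in names(mech_plan)) {
    k <- mech_plan[[sp]][["nhej"]]
    if (k == 0L) { nhej_targets[[sp]] <- anc_introns[0, ]; next }
    idx <- sample(seq_len(nrow(anc_introns)), k)
    nhej_targets[[sp]] <- anc_introns[idx, ]
  }
  planted_repeat <- stats::setNames(rep(NA_integer_, 0L), character(0))
  all_targets <- unique(do.call(rbind, nhej_targets)[, c("gene_index",
                                                         "ordinal")])
  if (nrow(all_targets) > 0L) {
    for (i in seq_len(nrow(all_targets))) {
      g <- all_targets$gene_index[i]; o <- all_targets$ordinal[i]
      r <- sample(2:6, 1L)
      ex <- anc[[g]]$exons[o]
      intr <- anc[[g]]$introns[o]
      tail_ex <- substr(ex, nchar(ex) - r + 1L, nchar(ex))
      anc[[g]]$introns[o] <- paste0(
        substr(intr, 1L, nchar(intr) - r), tail_ex)
      planted_repeat[paste(g, o)] <- r
    }
  }

  ## ---- per-species copies and event application --------------------
  species <- stats::setNames(
    lapply(SIM_SPECIES, function(sp) lapply(anc, function(g) g)),
    SIM_SPECIES)
  events <- list()
  record <- function(...) {
    events[[length(events) + 1L]] <<- data.frame(...)
  }

  remove_intron <- function(g, j, trim = 0L) {
    ## merge exons j, j+1 after trimming `trim` bp off the upstream tail
    up <- g$exons[j]
    if (trim > 0L) up <- substr(up, 1L, nchar(up) - trim)
    merged <- paste0(up, g$exons[j + 1L])
    g$exons <- append(g$exons[-c(j, j + 1L)], merged, after = j - 1L)
    g$introns <- g$introns[-j]
    g$anc_ord <- g$anc_ord[-j]
    g
  }

  for (sp in names(cfg$loss_counts)) {
    plan <- mech_plan[[sp]]
    ## NHEJ losses first (targets fixed above)
    tg <- nhej_targets[[sp]]
    for (i in seq_len(nrow(tg))) {
      g <- tg$gene_index[i]
      j <- match(tg$ordinal[i], species[[sp]][[g]]$anc_ord)
      record(type = "loss", species = sp, gene_index = g,
             anc_ordinal = tg$ordinal[i],
             anc_offset = anc_introns$cds_offset[
               anc_introns$gene_index == g &
                 anc_introns$ordinal == tg$ordinal[i]],
             mechanism = "nhej", precise = TRUE, flank_indel_bp = 0L,
             repeat_len = planted_repeat[[paste(g, tg$ordinal[i])]],
             source_id = NA_character_, focal_offset = NA_integer_)
      species[[sp]][[g]] <- remove_intron(species[[sp]][[g]], j)
    }
    ## RT and deletion losses, interleaved at random
    queue <- sample(c(rep("reverse_transcription",
                          plan[["reverse_transcription"]]),
                      rep("genomic_deletion", plan[["genomic_deletion"]])))
    done <- 0L
    budget <- length(queue)
    qi <- 1L
    while (done < budget) {
      mech <- queue[qi]
      n_remaining <- vapply(species[[sp]],
                            function(g) length(g$introns), integer(1))
      with_introns <- which(n_remaining > 0L)
      if (length(with_introns) == 0L) stop("intron pool exhausted")
      ## weight by intron count: each remaining intron equally likely to
      ## sit in the chosen transcript
      g <- if (length(with_introns) == 1L) with_introns else
        sample(with_introns, 1L, prob = n_remaining[with_introns])
      gene <- species[[sp]][[g]]
      offs <- gene_offsets(gene)
      L <- sum(nchar(gene$exons))
      if (mech == "reverse_transcription") {
        d <- if (stats::runif(1L) < cfg$rt_3prime_bias)
          stats::rexp(1L, 1 / cfg$partial_cdna_scale) else Inf
        cand <- which(offs >= L - d)
        if (length(cand) == 0L) cand <- length(offs)  # 3'-most
        coloss <- stats::runif(1L) < cfg$rt_coloss_prob
        take <- if (coloss) cand else
          (if (length(cand) == 1L) cand else sample(cand, 1L))
        take <- utils::tail(sort(take), budget - done)  # respect budget
        for (j in rev(sort(take))) {  # remove 3'-most first: stable indices
          record(type = "loss", species = sp, gene_index = g,
                 anc_ordinal = gene$anc_ord[j],
                 anc_offset = anc_introns$cds_offset[
                   anc_introns$gene_index == g &
                     anc_introns$ordinal == gene$anc_ord[j]],
                 mechanism = "reverse_transcription", precise = TRUE,
                 flank_indel_bp = 0L, repeat_len = NA_integer_,
                 source_id = NA_character_, focal_offset = NA_integer_)
          junction <- offs[j]
          species[[sp]][[g]] <- remove_intron(species[[sp]][[g]], j)
          if (cfg$gc_elevation_at_loss > 0) {
            ## junction now sits inside merged exon j
            gg <- species[[sp]][[g]]
            pre <- if (j > 1L) sum(nchar(gg$exons[seq_len(j - 1L)])) else 0L
            gg$exons[j] <- elevate_gc(gg$exons[j], junction - pre,
                                      cfg$gc_elevation_at_loss)
            species[[sp]][[g]] <- gg
          }
          done <- done + 1L
          qi <- qi + 1L
          if (done >= budget) break
        }
      } else {  # genomic_deletion
        j <- if (length(offs) == 1L) 1L else sample(seq_along(offs), 1L)
        indel <- sample(c(3L, 6L), 1L)
        if (nchar(gene$exons[j]) <= indel + 3L) next  # exon too short
        record(type = "loss", species = sp, gene_index = g,
               anc_ordinal = gene$anc_ord[j],
               anc_offset = anc_introns$cds_offset[
                 anc_introns$gene_index == g &
                   anc_introns$ordinal == gene$anc_ord[j]],
               mechanism = "genomic_deletion", precise = FALSE,
               flank_indel_bp = indel, repeat_len = NA_integer_,
               source_id = NA_character_, focal_offset = NA_integer_)
        species[[sp]][[g]] <- remove_intron(species[[sp]][[g]], j, indel)
        done <- done + 1L
        qi <- qi + 1L
      }
    }
  }

  ## ---- gains --------------------------------------------------------
  for (sp in names(cfg$gain_counts)) {
    k <- cfg$gain_counts[[sp]]
    for (i in seq_len(k)) {
      ## donor intron: any extant intron of another gene in this species
      donors <- which(vapply(species[[sp]],
                             function(g) length(g$introns) > 0L,
                             logical(1)))
      g <- sample(seq_len(n_genes), 1L)
      donors <- setdiff(donors, g)
      if (length(donors) == 0L) next
      dg <- if (length(donors) == 1L) donors else sample(donors, 1L)
      gene <- species[[sp]][[g]]
      dgene <- species[[sp]][[dg]]
      dj <- if (length(dgene$introns) == 1L) 1L else
        sample(seq_along(dgene$introns), 1L)
      donor_seq <- dgene$introns[dj]
      need <- min(nchar(donor_seq) - 4L,
                  max(8L, round(stats::rlnorm(1L, cfg$intron_len_meanlog,
                                              cfg$intron_len_sdlog)) - 4L))
      new_seq <- paste0("GT", substr(donor_seq, 3L, 2L + need), "AG")
      ## insertion point: interior of a random exon
      ex_ok <- which(nchar(gene$exons) > 20L)
      if (length(ex_ok) == 0L) next
      e <- if (length(ex_ok) == 1L) ex_ok else sample(ex_ok, 1L)
      cut <- sample(10:(nchar(gene$exons[e]) - 10L), 1L)
      pre <- if (e > 1L) sum(nchar(gene$exons[seq_len(e - 1L)])) else 0L
      offset <- pre + cut
      gene$exons <- append(
        append(gene$exons[-e], substr(gene$exons[e], 1L, cut),
               after = e - 1L),
        substr(gene$exons[e], cut + 1L, nchar(gene$exons[e])), after = e)
      gene$introns <- append(gene$introns, new_seq, after = e - 1L)
      gene$anc_ord <- append(gene$anc_ord, -i, after = e - 1L)  # gain mark
      species[[sp]][[g]] <- gene
      record(type = "gain", species = sp, gene_index = g,
             anc_ordinal = NA_integer_, anc_offset = NA_integer_,
             mechanism = "gain", precise = NA, flank_indel_bp = NA_integer_,
             repeat_len = NA_integer_,
             source_id = sprintf("%s_g%04d:i%d", sp, dg, dj),
             focal_offset = offset)
    }
  }

  ## ---- substitutions and stop repair --------------------------------
  for (sp in SIM_SPECIES) {
    rate <- cfg$subst_rate * SIM_SUBST_MULT[[sp]]
    for (g in seq_len(n_genes)) {
      gene <- species[[sp]][[g]]
      if (rate > 0) {
        gene$exons <- vapply(gene$exons, substitute_bases, character(1),
                             rate = rate, USE.NAMES = FALSE)
        gene$introns <- vapply(gene$introns, substitute_bases, character(1),
                               rate = rate, protect_head = 2L,
                               protect_tail = 2L, USE.NAMES = FALSE)
      }
      gene$exons <- fix_stops(gene$exons)
      species[[sp]][[g]] <- gene
    }
  }

  ## ---- assemble genomes, models, junctions --------------------------
  assembled <- stats::setNames(vector("list", length(SIM_SPECIES)),
                               SIM_SPECIES)
  for (sp in SIM_SPECIES) {
    chrom <- sprintf("%s_chr1", sp)
    pieces <- character(2L * n_genes)
    pos <- 0L
    models <- list()
    acc <- list()  # per-gene intron-table fragments (atomic vectors)
    for (g in seq_len(n_genes)) {
      gene <- species[[sp]][[g]]
      pieces[2L * g - 1L] <- rand_dna(200L, 0.3)
      pos <- pos + 200L
      gene_id <- sprintf("%s_g%04d", sp, g)
      n_int <- length(gene$introns)
      offs_sp <- if (n_int > 0L)
        cumsum(nchar(gene$exons))[seq_len(n_int)] else integer(0)
      n_ex <- length(gene$exons)
      tparts <- character(n_ex + n_int)
      tparts[seq(1L, by = 2L, length.out = n_ex)] <- gene$exons
      if (n_int > 0L) {
        tparts[seq(2L, by = 2L, length.out = n_int)] <- gene$introns
      }
      block <- paste(tparts, collapse = "")
      Lb <- nchar(block)
      tlens <- nchar(tparts)
      tends <- cumsum(tlens)
      tstarts <- c(0L, utils::head(tends, -1L))
      if (anc[[g]]$strand == "+") {
        g0 <- pos + tstarts
        g1 <- pos + tends
      } else {
        g0 <- pos + Lb - tends
        g1 <- pos + Lb - tstarts
      }
      ex_idx <- seq(1L, by = 2L, length.out = n_ex)
      seg <- cbind(start = g0[ex_idx], end = g1[ex_idx])
      if (n_int > 0L) {
        in_idx <- seq(2L, by = 2L, length.out = n_int)
        acc[[length(acc) + 1L]] <- list(
          gene_id = rep(gene_id, n_int), gene_index = rep(g, n_int),
          ordinal = seq_len(n_int), anc_ordinal = gene$anc_ord,
          cds_offset = offs_sp, gstart = g0[in_idx], gend = g1[in_idx],
          length = tlens[in_idx], sequence = tparts[in_idx])
      }
      spliced <- paste(gene$exons, collapse = "")
      models[[gene_id]] <- new_gene_model(
        gene_id, sp, chrom, anc[[g]]$strand, seg, spliced,
        sub("\\*$", "", translate_cds(spliced)))
      pieces[2L * g] <- if (anc[[g]]$strand == "+") block else
        revcomp_chr(block)
      pos <- pos + Lb
    }
    genome <- Biostrings::DNAStringSet(paste(pieces, collapse = ""))
    names(genome) <- chrom
    col <- function(nm) unlist(lapply(acc, `[[`, nm), use.names = FALSE)
    intr_tab <- if (length(acc) > 0L) data.frame(
      gene_id = col("gene_id"), gene_index = col("gene_index"),
      ordinal = col("ordinal"), anc_ordinal = col("anc_ordinal"),
      cds_offset = col("cds_offset"), phase = col("cds_offset") %% 3L,
      chrom = chrom, gstart = col("gstart"), gend = col("gend"),
      length = col("length"), sequence = col("sequence")) else NULL
    assembled[[sp]] <- list(
      genome = genome, models = models,
      junctions = if (is.null(intr_tab)) NULL else data.frame(
        chrom = chrom, start = intr_tab$gstart, end = intr_tab$gend,
        count = 10),
      introns = intr_tab)
  }

  ## ---- synthetic hit tables -----------------------------------------
  make_hits <- function(sp_a, sp_b) {
    qa <- sprintf("%s_g%04d", sp_a, seq_len(n_genes))
    qb <- sprintf("%s_g%04d", sp_b, seq_len(n_genes))
    plen <- vapply(assembled[[sp_a]]$models[qa],
                   function(m) nchar(m$protein), integer(1))
    data.frame(query_id = qa, subject_id = qb, percent_identity = 90,
               aln_length = plen, mismatch = 0L, gapopen = 0L,
               qstart = 1L, qend = plen, sstart = 1L, send = plen,
               evalue = 1e-50, bitscore = 300)
  }
  hits <- list()
  for (sp in setdiff(SIM_SPECIES, "DDB")) {
    hits[[paste0("DDB_", sp)]] <- make_hits("DDB", sp)
    hits[[paste0(sp, "_DDB")]] <- make_hits(sp, "DDB")
  }

  ## gain-source hit table: true source hit plus the trivial self-hit
  events_df <- if (length(events)) do.call(rbind, events) else
    data.frame(type = character(), species = character(),
               gene_index = integer(), anc_ordinal = integer(),
               anc_offset = integer(), mechanism = character(),
               precise = logical(), flank_indel_bp = integer(),
               repeat_len = integer(), source_id = character(),
               focal_offset = integer())
  gain_hits <- list()
  gain_info <- list()
  gev <- events_df[events_df$type == "gain", , drop = FALSE]
  for (i in seq_len(nrow(gev))) {
    sp <- gev$species[i]
    g <- gev$gene_index[i]
    tab <- assembled[[sp]]$introns
    row <- tab[tab$gene_index == g & tab$anc_ordinal < 0 &
                 tab$cds_offset == gev$focal_offset[i], , drop = FALSE]
    if (nrow(row) != 1L) next
    row <- row[1, ]  # focal gained intron
    src <- strsplit(gev$source_id[i], ":i", fixed = TRUE)[[1]]
    sg <- as.integer(sub(".*_g", "", src[1]))
    stab <- assembled[[sp]]$introns
    srow <- stab[stab$gene_id == src[1] &
                   stab$ordinal == as.integer(src[2]), , drop = FALSE]
    iid <- sprintf("%s:gain%d", row$gene_id, row$ordinal)
    gain_info[[length(gain_info) + 1L]] <- data.frame(
      intron_id = iid, length = row$length, chrom = row$chrom,
      gstart = row$gstart, gend = row$gend)
    add_hit <- function(subj, s0, s1, pid, ev) {
      gain_hits[[length(gain_hits) + 1L]] <<- data.frame(
        query_id = iid, subject_id = subj, percent_identity = pid,
        aln_length = row$length, mismatch = 0L, gapopen = 0L, qstart = 1L,
        qend = row$length, sstart = s0 + 1L, send = s1, evalue = ev,
        bitscore = 200)
    }
    add_hit(row$chrom, row$gstart, row$gend, 100, 0)          # self
    if (nrow(srow) == 1L) {
      add_hit(srow$chrom, srow$gstart, srow$gend, 97, 1e-30)  # true source
    }
  }
  gain_hits <- if (length(gain_hits)) do.call(rbind, gain_hits) else NULL
  gain_info <- if (length(gain_info)) do.call(rbind, gain_info) else NULL

  species_introns <- do.call(rbind, lapply(SIM_SPECIES, function(sp) {
    tab <- assembled[[sp]]$introns
    if (is.null(tab)) return(NULL)
    cbind(species = sp,
          tab[, c("gene_id", "gene_index", "ordinal", "anc_ordinal",
                  "cds_offset")])
  }))
  truth <- list(events = events_df, ancestral_introns = anc_introns,
                species_introns = species_introns,
                run_id = sprintf("sim-%d-%d", cfg$seed, cfg$n_genes))

  result <- list(species = assembled, hits = hits, gain_hits = gain_hits,
                 gain_intron_info = gain_info, truth = truth,
                 config = cfg)
  if (!is.null(out_dir)) write_simulation(result, out_dir)
  result
}

write_tsv <- function(df, path, col.names = TRUE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
}

#' Write a simulation to disk as standard-format files
#'
#' @param sim result of [simulate_clade()].
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(sim$species)) {
    s <- sim$species[[sp]]
    Biostrings::writeXStringSet(
      s$genome, file.path(out_dir, paste0(sp, ".fa")))
    write_gene_models_gff3(s$models, file.path(out_dir,
                                               paste0(sp, ".gff3")))
    jx <- s$junctions
    bed <- data.frame(chrom = jx$chrom, start = jx$start, end = jx$end,
                      name = sprintf("jx%05d", seq_len(nrow(jx))),
                      count = jx$count, strand = ".")
    write_tsv(bed, file.path(out_dir, paste0(sp, ".junctions.bed")),
              col.names = FALSE)
  }
  for (nm in names(sim$hits)) {
    write_tsv(sim$hits[[nm]],
              file.path(out_dir, paste0("hits_", nm, ".tsv")),
              col.names = FALSE)
  }
  if (!is.null(sim$gain_hits)) {
    write_tsv(sim$gain_hits, file.path(out_dir, "gain_source_hits.tsv"),
              col.names = FALSE)
    write_tsv(sim$gain_intron_info,
              file.path(out_dir, "gain_intron_info.tsv"))
  }
  write_tsv(sim$truth$events, file.path(out_dir, "truth_events.tsv"))
  write_tsv(sim$truth$ancestral_introns,
            file.path(out_dir, "truth_ancestral_introns.tsv"))
  write_tsv(sim$truth$species_introns,
            file.path(out_dir, "truth_species_introns.tsv"))
  writeLines(sim$truth$run_id, file.path(out_dir, "run_id.txt"))
  invisible(out_dir)
}
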