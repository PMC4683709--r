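test_that("an event-free clade is five identical annotation sets", {
  cfg <- sim_config(seed = 5, n_genes = 6,
                    loss_counts = c(DDB = 0L, DPU = 0L),
                    gain_counts = c(DDB = 0L, DPU = 0L),
                    subst_rate = 0)
  sim <- simulate_clade(cfg)
  expect_equal(nrow(sim$truth$events), 0)
  ref <- vapply(sim$species$DDB$models, function(m) m$spliced_cds,
                character(1))
  for (sp in c("DPU", "PPA", "DFA", "EHI")) {
    got <- vapply(sim$species[[sp]]$models, function(m) m$spliced_cds,
                  character(1))
    expect_equal(unname(got), unname(ref))
  }
  expect_equal(nrow(sim$species$DDB$introns),
               nrow(sim$species$EHI$introns))
})

test_that("the same seed reproduces the simulation byte for byte", {
  cfg <- sim_config(seed = 42, n_genes = 5,
                    loss_counts = c(DDB = 3L, DPU = 2L))
  s1 <- simulate_clade(cfg)
  s2 <- simulate_clade(cfg)
  expect_identical(as.character(s1$species$DDB$genome),
                   as.character(s2$species$DDB$genome))
  expect_identical(s1$truth$events, s2$truth$events)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("loss bookkeeping matches the requested budget", {
  cfg <- sim_config(seed = 8, n_genes = 40, introns_per_gene = c(2L, 10L),
                    loss_counts = c(DDB = 50L, DPU = 0L),
                    gain_counts = c(DDB = 0L, DPU = 0L))
  sim <- simulate_clade(cfg)
  ev <- sim$truth$events
  expect_equal(sum(ev$type == "loss" & ev$species == "DDB"), 50L)
  expect_equal(sum(ev$species == "DPU"), 0L)
  expect_true(all(ev$mechanism == "reverse_transcription"))
  # every simulated event has exactly one record
  expect_equal(anyDuplicated(ev[, c("species", "gene_index",
                                    "anc_ordinal")]), 0L)

  expect_error(simulate_clade(sim_config(seed = 1, n_genes = 2,
                                         introns_per_gene = c(1L, 2L),
                                         loss_counts = c(DDB = 50L,
                                                         DPU = 0L))),
               "more losses")
})

test_that("mechanism mix plants the expected signatures", {
  cfg <- sim_config(seed = 23, n_genes = 30, introns_per_gene = c(2L, 8L),
                    loss_counts = c(DDB = 12L, DPU = 0L),
                    mechanism_mix = c(reverse_transcription = 0,
                                      genomic_deletion = 0.5, nhej = 0.5),
                    gain_counts = c(DDB = 0L, DPU = 0L),
                    subst_rate = 0)
  sim <- simulate_clade(cfg)
  ev <- sim$truth$events
  expect_equal(sum(ev$mechanism == "genomic_deletion"), 6L)
  expect_equal(sum(ev$mechanism == "nhej"), 6L)
  expect_true(all(!ev$precise[ev$mechanism == "genomic_deletion"]))
  expect_true(all(ev$flank_indel_bp[ev$mechanism == "genomic_deletion"]
                  %in% c(3L, 6L)))
  # NHEJ targets carry their planted boundary repeat in the species that
  # kept the intron (DPU inherits the ancestral state)
  nh <- ev[ev$mechanism == "nhej", ]
  dpu <- sim$species$DPU
  for (i in seq_len(nrow(nh))) {
    tab <- dpu$introns
    row <- tab[tab$gene_index == nh$gene_index[i] &
                 tab$anc_ordinal == nh$anc_ordinal[i], ]
    if (nrow(row) != 1L) next  # lost in DPU too
    cds <- dpu$models[[row$gene_id]]$spliced_cds
    up <- substr(cds, max(1, row$cds_offset - 19), row$cds_offset)
    down <- substr(cds, row$cds_offset + 1, row$cds_offset + 20)
    r <- direct_repeat_length(up, row$sequence, down)
    expect_gte(r[["repeat_len_3p"]], nh$repeat_len[i])
  }
})

test_that("simulated files round-trip through the genome reader", {
  cfg <- sim_config(seed = 77, n_genes = 6,
                    loss_counts = c(DDB = 2L, DPU = 1L),
                    gain_counts = c(DDB = 1L, DPU = 0L))
  dir <- withr::local_tempdir()
  sim <- simulate_clade(cfg, out_dir = dir)
  for (sp in c("DDB", "EHI")) {
    genome <- read_genome_fasta(file.path(dir, paste0(sp, ".fa")))
    built <- build_gene_models(file.path(dir, paste0(sp, ".gff3")),
                               genome, sp)
    expect_equal(nrow(built$rejects), 0)
    for (gid in names(sim$species[[sp]]$models)) {
      expect_equal(built$models[[gid]]$spliced_cds,
                   sim$species[[sp]]$models[[gid]]$spliced_cds, label = gid)
    }
    # intron table re-derived from files matches the simulator's record
    introns <- do.call(rbind, lapply(built$models, extract_introns,
                                     genome = genome))
    ref <- sim$species[[sp]]$introns
    key <- function(d) paste(d$gene_id, d$cds_offset, d$length)
    expect_setequal(key(introns), key(ref))
  }
})

test_that("gain events record a findable source sequence", {
  cfg <- sim_config(seed = 19, n_genes = 12,
                    loss_counts = c(DDB = 0L, DPU = 0L),
                    gain_counts = c(DDB = 2L, DPU = 1L),
                    subst_rate = 0)
  sim <- simulate_clade(cfg)
  ev <- sim$truth$events
  expect_equal(sum(ev$type == "gain"), nrow(sim$gain_intron_info))
  out <- filter_source_hits(sim$gain_hits, sim$gain_intron_info)
  # per gained intron: the self-hit is rejected, the true source retained
  for (iid in sim$gain_intron_info$intron_id) {
    v <- out$verdict[out$intron_id == iid]
    expect_true("rejected_self" %in% v, label = iid)
    expect_true("retained" %in% v, label = iid)
  }
})
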