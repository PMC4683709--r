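test_that("FASTA reading normalises case and ambiguity codes", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "acgt"), f)
  g <- read_genome_fasta(f)
  expect_equal(as.character(g[["c1"]]), "ACGT")

  writeLines(c(">c1", "ACRT"), f)
  expect_warning(g <- read_genome_fasta(f), "ambiguous")
  expect_equal(as.character(g[["c1"]]), "ACNT")

  writeLines(c(">c1", "ACGT", ">c1", "TTTT"), f)
  expect_error(read_genome_fasta(f), "duplicate.*c1")

  writeLines(character(0), f)
  expect_error(read_genome_fasta(f))
})

test_that("gene models are built and validated from GFF3", {
  f <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  # chromosome: exon1 ATGAAA [0,6), gap, exon2 TTT [10,13) => MKF
  chrom <- paste0("ATGAAA", "GTAG", "TTT", "AAAAA")
  write_fasta_chr(c(c1 = chrom), f)
  plus_gff(gff, cbind(c(0L, 10L), c(6L, 13L)))
  built <- build_gene_models(gff, read_genome_fasta(f), "SP")
  expect_length(built$models, 1)
  m <- built$models[["gp1"]]
  expect_equal(m$spliced_cds, "ATGAAATTT")
  expect_equal(m$protein, "MKF")
  expect_equal(nrow(built$rejects), 0)

  # CDS of length 10: rejected as not a multiple of three
  plus_gff(gff, cbind(c(0L, 10L), c(6L, 14L)))
  built <- build_gene_models(gff, read_genome_fasta(f), "SP")
  expect_length(built$models, 0)
  expect_equal(built$rejects$reason, "not_mult3")

  # internal stop: TAA mid-frame
  write_fasta_chr(c(c1 = "ATGTAAAAATTT"), f)
  plus_gff(gff, cbind(0L, 12L))
  built <- build_gene_models(gff, read_genome_fasta(f), "SP")
  expect_equal(built$rejects$reason, "internal_stop")

  # unknown chromosome -> rejected, not a crash
  plus_gff(gff, cbind(0L, 12L), chrom = "cX")
  built <- build_gene_models(gff, read_genome_fasta(f), "SP")
  expect_equal(built$rejects$reason, "out_of_bounds")
})

test_that("minus-strand genes splice and translate in transcript order", {
  f <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_fasta_chr(c(c1 = toy_minus_chrom()), f)
  toy_minus_gff(gff)
  built <- build_gene_models(gff, read_genome_fasta(f), "SP")
  m <- built$models[["gm1"]]
  expect_equal(m$strand, "-")
  expect_equal(m$spliced_cds, "ATGAAATTTGGGCCCTAA")
  expect_equal(m$protein, "MKFGP")
  # transcript order: first segment is the genomically later one
  expect_equal(m$cds_segments[1, ], c(start = 20L, end = 29L))
  expect_equal(m$cds_segments[2, ], c(start = 5L, end = 14L))
})

test_that("introns carry offsets, phases, lengths and sequences", {
  # single-exon gene: no introns
  m1 <- model_from_cds("ATGAAATTT")
  expect_equal(nrow(extract_introns(m1)), 0)

  # plus strand, segments [0,10) and [130,160)
  m2 <- intronevo:::new_gene_model(
    "g2", "SP", "c1", "+", cbind(start = c(0L, 130L), end = c(10L, 160L)),
    strrep("A", 40), "X")
  introns <- extract_introns(m2)
  expect_equal(introns$cds_offset, 10L)
  expect_equal(introns$phase, 1L)
  expect_equal(introns$length, 120L)

  # minus-strand toy: intron sequence is the reverse complement of the gap
  f <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_fasta_chr(c(c1 = toy_minus_chrom()), f)
  toy_minus_gff(gff)
  genome <- read_genome_fasta(f)
  m <- build_gene_models(gff, genome, "SP")$models[["gm1"]]
  introns <- extract_introns(m, genome)
  expect_equal(introns$sequence, "GTTTAG")
  expect_equal(introns$cds_offset, 9L)
  expect_equal(introns$phase, 0L)
  expect_equal(introns$donor2, "GT")
  expect_equal(introns$acceptor2, "AG")

  # overlapping segments are an error
  bad <- intronevo:::new_gene_model(
    "g3", "SP", "c1", "+", cbind(start = c(0L, 5L), end = c(10L, 20L)),
    strrep("A", 25), "X")
  expect_error(extract_introns(bad), "overlapping")
})

test_that("GFF3 round-trip preserves segments and strand; intron lengths sum", {
  sim <- simulate_clade(sim_config(seed = 11, n_genes = 8,
                                   loss_counts = c(DDB = 2L, DPU = 1L),
                                   gain_counts = c(DDB = 0L, DPU = 0L),
                                   subst_rate = 0))
  sp <- sim$species$DDB
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models_gff3(sp$models, gff)
  rebuilt <- build_gene_models(gff, sp$genome, "DDB")
  expect_setequal(names(rebuilt$models), names(sp$models))
  for (gid in names(sp$models)) {
    a <- sp$models[[gid]]
    b <- rebuilt$models[[gid]]
    expect_equal(unname(a$cds_segments), unname(b$cds_segments))
    expect_equal(a$strand, b$strand)
    expect_equal(a$spliced_cds, b$spliced_cds)
    introns <- extract_introns(b, sp$genome)
    # phases are offsets mod 3; lengths fill the genomic CDS span
    expect_equal(introns$phase, introns$cds_offset %% 3L)
    span <- max(b$cds_segments[, 2]) - min(b$cds_segments[, 1])
    expect_equal(sum(introns$length) + nchar(b$spliced_cds), span)
  }
})
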