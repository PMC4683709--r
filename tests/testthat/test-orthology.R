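hit <- function(q, s, pid = 90, len = 100, ev = 1e-50, bs = 200) {
  data.frame(query_id = q, subject_id = s, percent_identity = pid,
             aln_length = len, mismatch = 0L, gapopen = 0L, qstart = 1L,
             qend = len, sstart = 1L, send = len, evalue = ev,
             bitscore = bs)
}

test_that("reciprocal best hits honour thresholds and reciprocity", {
  ab <- rbind(hit("a1", "b1"), hit("a2", "b2", ev = 1e-9))
  ba <- rbind(hit("b1", "a1"), hit("b2", "a2"))
  pairs <- reciprocal_best_hits(ab, ba)
  # a2/b2 fails the E-value threshold before best-hit selection
  expect_equal(pairs, data.frame(gene_a = "a1", gene_b = "b1"),
               ignore_attr = TRUE)

  # identity below 25% filtered
  pairs <- reciprocal_best_hits(hit("a1", "b1", pid = 20),
                                hit("b1", "a1", pid = 20))
  expect_equal(nrow(pairs), 0)

  # non-reciprocal best: a1 -> b1 but b1 -> a2
  ab <- rbind(hit("a1", "b1", bs = 300))
  ba <- rbind(hit("b1", "a1", bs = 100), hit("b1", "a2", bs = 300))
  expect_equal(nrow(reciprocal_best_hits(ab, ba)), 0)

  # full tie broken lexicographically, with a logged flag
  ab <- rbind(hit("a1", "b2"), hit("a1", "b1"))
  ba <- rbind(hit("b1", "a1"), hit("b2", "a1"))
  expect_message(pairs <- reciprocal_best_hits(ab, ba), "ambiguous")
  expect_equal(pairs$gene_b, "b1")
})

test_that("RBH is symmetric in the two species", {
  set.seed(5)
  ab <- do.call(rbind, lapply(1:8, function(i) {
    hit(paste0("a", i), paste0("b", sample(8, 1)),
        bs = sample(100:300, 1))
  }))
  ba <- do.call(rbind, lapply(1:8, function(i) {
    hit(paste0("b", i), paste0("a", sample(8, 1)),
        bs = sample(100:300, 1))
  }))
  p1 <- reciprocal_best_hits(ab, ba)
  p2 <- reciprocal_best_hits(ba, ab)
  expect_equal(p1$gene_a, sort(p2$gene_b))
  expect_equal(nrow(p1), nrow(p2))
})

test_that("protein alignment is global, affine, and matches a DP oracle", {
  id <- align_proteins("MKVLL", "MKVLL")
  expect_equal(id$aligned_a, "MKVLL")
  expect_equal(id$aligned_b, "MKVLL")

  one_gap <- align_proteins("MKV", "MV")
  expect_equal(nchar(one_gap$aligned_a), 3)
  expect_equal(sum(strsplit(one_gap$aligned_b, "")[[1]] == "-"), 1)

  set.seed(31)
  for (i in 1:15) {
    a <- random_protein(sample(2:10, 1))
    b <- random_protein(sample(2:10, 1))
    got <- align_proteins(a, b)$score
    expect_equal(got, nw_affine_score(a, b), tolerance = 1e-9,
                 info = paste(a, b))
  }
})

test_that("codon expansion keeps tiers consistent", {
  ga <- model_from_cds("ATGAAAGTT")   # MKV
  gb <- model_from_cds("ATGGTT")      # MV
  aln <- codon_alignment(ga, gb)
  expect_equal(nchar(aln$aligned_cds_a), 3 * nchar(aln$aligned_protein_a))
  expect_equal(gsub("-", "", aln$aligned_cds_a), ga$spliced_cds)
  expect_equal(gsub("-", "", aln$aligned_cds_b), gb$spliced_cds)
})

test_that("intron sites project to columns and split by phase", {
  cds <- strrep("ATGAAAGTTCCA", 3)
  g <- model_from_cds(cds)
  aln <- codon_alignment(g, g)
  # same offset in both genes: one conserved site
  sites <- project_intron_sites(aln, intron_row("ga", 1, 10),
                                intron_row("gb", 1, 10))
  expect_equal(sites$status, "conserved")
  expect_equal(sites$column, 10L)

  # intron only in species a
  sites <- project_intron_sites(aln, intron_row("ga", 1, 10),
                                intron_row("gb", 1, 10)[0, ])
  expect_equal(sites$status, "discordant_a_only")

  # same aligned column but different phase: two discordant sites
  m <- manual_alignment(strrep("A", 12), strrep("A", 12))
  sites <- project_intron_sites(m, intron_row("ga", 1, 10, phase = 1),
                                intron_row("gb", 1, 10, phase = 2))
  expect_equal(nrow(sites), 2)
  expect_setequal(sites$status,
                  c("discordant_a_only", "discordant_b_only"))

  # offset beyond CDS length errors with the gene named
  expect_error(project_intron_sites(m, intron_row("ga", 1, 50),
                                    intron_row("gb", 1, 10)[0, ]),
               "ga")
})

test_that("projection against self is all-conserved and conserves counts", {
  sim <- simulate_clade(sim_config(seed = 2, n_genes = 6,
                                   loss_counts = c(DDB = 3L, DPU = 2L),
                                   gain_counts = c(DDB = 1L, DPU = 0L),
                                   subst_rate = 0.02))
  ddb <- sim$species$DDB
  dpu <- sim$species$DPU
  for (g in seq_len(3)) {
    ga <- ddb$models[[g]]
    ia <- ddb$introns[ddb$introns$gene_id == ga$gene_id, ]
    aln_self <- codon_alignment(ga, ga)
    self_sites <- project_intron_sites(aln_self, ia, ia)
    expect_true(all(self_sites$status == "conserved"))
    expect_equal(nrow(self_sites), nrow(ia))

    gb <- dpu$models[[g]]
    ib <- dpu$introns[dpu$introns$gene_id == gb$gene_id, ]
    sites <- project_intron_sites(codon_alignment(ga, gb), ia, ib)
    n_cons <- sum(sites$status == "conserved")
    # every input intron appears in exactly one site call
    expect_equal(2 * n_cons + sum(sites$status != "conserved"),
                 nrow(ia) + nrow(ib))
  }
})

test_that("flank similarity counts identical non-gap columns per side", {
  a <- paste0(strrep("A", 45), strrep("C", 45))
  m <- manual_alignment(a, a)
  expect_equal(unname(flank_similarity(m, 45)), c(1, 1))

  b <- paste0(strrep("T", 45), strrep("C", 45))
  m2 <- manual_alignment(a, b)  # left flank fully mismatched
  expect_equal(unname(flank_similarity(m2, 45)), c(0, 1))

  # 27 identities of 45 on the left
  b3 <- paste0(strrep("A", 27), strrep("T", 18), strrep("C", 45))
  m3 <- manual_alignment(a, b3)
  expect_equal(unname(flank_similarity(m3, 45))[1], 0.6)

  # truncated window: only 10 columns available on the left
  m4 <- manual_alignment(strrep("A", 100), strrep("A", 100))
  expect_equal(unname(flank_similarity(m4, 10))[1], 1)
})

test_that("low-quality sites are discarded and Q1 is reported", {
  sites <- data.frame(status = rep("conserved", 3),
                      sim_left = c(0.9, 0.4, 0.9),
                      sim_right = c(0.9, 0.9, 0.45))
  out <- filter_sites(sites, alignment_similarities = c(0.2, 0.4, 0.6, 0.8))
  expect_equal(out$status,
               c("conserved", "discarded_low_quality",
                 "discarded_low_quality"))
  expect_equal(attr(out, "q1"), 0.35)
})

test_that("junction evidence confirms or discards discordant introns", {
  sites <- data.frame(
    status = c("discordant_a_only", "discordant_a_only", "conserved"),
    chrom_a = "c1", gstart_a = c(100L, 200L, 300L),
    gend_a = c(150L, 260L, 360L),
    chrom_b = NA_character_, gstart_b = NA_integer_, gend_b = NA_integer_)
  jx <- data.frame(chrom = "c1", start = c(100L, 201L),
                   end = c(150L, 260L), count = c(5, 9))
  out <- junction_filter(sites, junctions_a = jx, junctions_b = NULL)
  expect_equal(out$status[1], "discordant_a_only")    # exact match
  expect_equal(out$status[2], "discarded_junction")   # off by one
  expect_equal(out$status[3], "conserved")            # untouched

  # absent junction data: evidence absent is not evidence against
  expect_message(out2 <- junction_filter(sites, NULL, NULL),
                 "retained")
  expect_equal(out2$status, sites$status)
})

test_that("BED junctions parse from 6-column and BED12 forms", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("c1\t100\t150\tj1\t7\t+",
               "c1\t0\t500\tj2\t3\t+\t0\t500\t0\t2\t50,100\t0,400"), f)
  jx <- read_junctions_bed(f)
  expect_equal(nrow(jx), 2)
  expect_equal(jx$start, c(100L, 50L))
  expect_equal(jx$end, c(150L, 400L))
  expect_equal(jx$count, c(7, 3))

  writeLines("c1\tnotanumber\t5\tj\t1\t+", f)
  expect_error(read_junctions_bed(f), "line 1")
})
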