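test_that("precision classification inspects a window of aligned columns", {
  clean <- manual_alignment(strrep("A", 60), strrep("A", 60))
  res <- classify_precision(clean, 30)
  expect_true(res$precise)
  expect_equal(res$flank_indel_bp, 0L)

  # a 3-column gap right next to the site: imprecise, 3 bp
  gapped <- manual_alignment(
    paste0(strrep("A", 30), "---", strrep("A", 27)),
    strrep("A", 60))
  res <- classify_precision(gapped, 30)
  expect_false(res$precise)
  expect_equal(res$flank_indel_bp, 3L)

  # the same gap 20 columns away is outside the 15-column window
  far <- manual_alignment(
    paste0(strrep("A", 50), "---", strrep("A", 27)),
    strrep("A", 80))
  expect_true(classify_precision(far, 30)$precise)
})

test_that("adjacent losses are counted as consecutive-ordinal pairs", {
  expect_equal(adjacent_loss_pairs(
    data.frame(gene_id = "g", ordinal = c(4, 5, 6))), 2L)
  expect_equal(adjacent_loss_pairs(
    data.frame(gene_id = "g", ordinal = c(1, 3))), 0L)
  expect_equal(adjacent_loss_pairs(
    data.frame(gene_id = "g", ordinal = c(2, 3, 7, 8))), 2L)
  expect_equal(adjacent_loss_pairs(
    data.frame(gene_id = c("g1", "g2"), ordinal = c(2, 3))), 0L)

  # k losses in one gene give between 0 and k-1 pairs; k-1 iff consecutive
  set.seed(12)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    ords <- sort(sample(1:12, k))
    p <- adjacent_loss_pairs(data.frame(gene_id = "g", ordinal = ords))
    expect_gte(p, 0L)
    expect_lte(p, k - 1L)
    expect_equal(p == k - 1L, all(diff(ords) == 1L))
  }
})

test_that("direct repeats are longest shared boundary prefixes/suffixes", {
  r <- direct_repeat_length("AAACAG", "GTTTTTCAG", "ATTT")
  expect_equal(r[["repeat_len_3p"]], 3L)   # CAG repeated

  r <- direct_repeat_length("AAAA", "GTAACCC", "GTTT")
  expect_equal(r[["repeat_len_5p"]], 2L)   # GT repeated

  r <- direct_repeat_length("CCCC", "GTAAAG", "TTTT")
  expect_equal(unname(r), c(0L, 0L))

  # capped at available sequence and k_max
  r <- direct_repeat_length("AG", "GTAG", "GTAG")
  expect_lte(r[["repeat_len_3p"]], 2L)
  long <- strrep("A", 30)
  r <- direct_repeat_length(long, long, long)
  expect_equal(unname(r), c(10L, 10L))
})

test_that("repeat frequency comparison builds the 2x2 test", {
  same <- repeat_frequency_compare(rep(c(0, 5), c(90, 10)),
                                   rep(c(0, 5), c(90, 10)), k = 3)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  r <- repeat_frequency_compare(rep(c(5, 0), c(30, 70)),
                                rep(c(5, 0), c(10, 90)), k = 3)
  oracle <- chi2_scalar(30, 70, 10, 90)
  expect_equal(r$chi2, oracle$chi2, tolerance = 1e-12)
  expect_equal(r$p, oracle$p, tolerance = 1e-12)
})

test_that("relative intron position is offset over spliced length", {
  expect_equal(relative_intron_position(250, 1000), 0.25)
  expect_equal(relative_intron_position(3, 300), 0.01)
  offs <- cumsum(rep(120, 6))
  pos <- relative_intron_position(offs, 1000)
  expect_true(all(diff(pos) > 0))
})

test_that("flank GC pools exonic windows and truncates at CDS ends", {
  cds <- paste0(strrep("AT", 100), strrep("GC", 100))
  expect_equal(flank_gc(cds, 100, window = 50)$gc, 0)
  expect_equal(flank_gc(cds, 300, window = 50)$gc, 1)

  # site 30 bp from the start: left window truncated, denominator 130
  cds2 <- paste0(strrep("A", 30), strrep("G", 50), strrep("A", 50),
                 strrep("T", 100))
  gc <- flank_gc(cds2, 30, window = 100)
  expect_equal(gc$gc, 50 / 130)
  expect_equal(nchar(gc$left_seq), 30)

  # N bases drop out of the denominator
  expect_equal(flank_gc("AANNGG", 3, window = 3)$gc, 2 / 4)

  # window-200 call equals plain GC of the concatenated 400 bp
  set.seed(3)
  cds3 <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                collapse = "")
  both <- paste0(substr(cds3, 101, 300), substr(cds3, 301, 500))
  expect_equal(flank_gc(cds3, 300, window = 200)$gc, gc_fraction(both))
})

test_that("relative flank GC normalises by same-gene conserved median", {
  expect_equal(relative_flank_gc(0.30, 0.25), 1.2)
  expect_equal(relative_flank_gc(0.4, 0.4), 1)
  expect_equal(relative_flank_gc(0.3, c(0.2, 0.3, 0.4)), 1)
  expect_true(is.na(relative_flank_gc(0.3, numeric(0))))
  expect_warning(out <- relative_flank_gc(0.3, c(0, 0)), "zero")
  expect_true(is.na(out))
})

test_that("4-fold-site GC reads third positions of degenerate codons", {
  # codons GTA GTC upstream of the site: thirds {A, C} -> 0.5
  expect_equal(fourfold_gc("GTAGTCAAA", 6, window = 6), 0.5)
  # no 4-fold codon in window
  expect_true(is.na(fourfold_gc("ATGTGGATGTGG", 6, window = 6)))
  # all-GGG windows
  expect_equal(fourfold_gc(strrep("GGG", 20), 30, window = 15), 1)
  # partial codons at window edges are trimmed, not misread
  expect_equal(fourfold_gc("AAGTAGTCAAA", 8, window = 7),
               fourfold_gc("AAGTAGTCAAA", 8, window = 6))
})
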