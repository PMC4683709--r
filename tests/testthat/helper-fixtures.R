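# Toy genome/annotation fixtures built in code.

write_fasta_chr <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(seqs[[nm]], con)
  }
  path
}

# Hand-constructed minus-strand two-exon gene:
#   transcript CDS  = ATGAAATTT | GGGCCCTAA  (MKFGP*)
#   transcript intron = GTTTAG (canonical GT..AG)
# laid out on the minus strand of a 40 bp chromosome.
toy_minus_chrom <- function() {
  paste0("AAAAA",        # 0-4
         "TTAGGGCCC",    # 5-13  = revcomp(GGGCCCTAA), exon 2
         "CTAAAC",       # 14-19 = revcomp(GTTTAG), intron
         "AAATTTCAT",    # 20-28 = revcomp(ATGAAATTT), exon 1
         "GGGGGGGGGGG")  # 29-39
}

toy_minus_gff <- function(path) {
  lines <- c(
    "##gff-version 3",
    "c1\ttoy\tgene\t6\t29\t.\t-\t.\tID=gm1",
    "c1\ttoy\tmRNA\t6\t29\t.\t-\t.\tID=gm1.t1;Parent=gm1",
    "c1\ttoy\tCDS\t21\t29\t.\t-\t0\tID=c1x;Parent=gm1.t1",
    "c1\ttoy\tCDS\t6\t14\t.\t-\t0\tID=c2x;Parent=gm1.t1")
  writeLines(lines, path)
  path
}

# plus-strand gene with arbitrary CDS segments on a supplied chromosome
plus_gff <- function(path, segments, gene_id = "gp1", chrom = "c1",
                     extra = NULL) {
  lo <- min(segments[, 1]) + 1L
  hi <- max(segments[, 2])
  lines <- c("##gff-version 3",
             sprintf("%s\ttoy\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                     chrom, lo, hi, gene_id),
             sprintf("%s\ttoy\tmRNA\t%d\t%d\t.\t+\t.\tID=%s.t1;Parent=%s",
                     chrom, lo, hi, gene_id, gene_id))
  for (i in seq_len(nrow(segments))) {
    lines <- c(lines, sprintf(
      "%s\ttoy\tCDS\t%d\t%d\t.\t+\t0\tID=%s.c%d;Parent=%s.t1",
      chrom, segments[i, 1] + 1L, segments[i, 2], gene_id, i, gene_id))
  }
  if (!is.null(extra)) lines <- c(lines, extra)
  writeLines(lines, path)
  path
}

# minimal gene_model directly from a spliced CDS (no genome needed)
model_from_cds <- function(cds, gene_id = "g", species = "SP") {
  intronevo:::new_gene_model(
    gene_id, species, "chr", "+",
    cbind(start = 0L, end = nchar(cds)), cds,
    sub("\\*$", "", intronevo:::translate_cds(cds)))
}

# intron table row for project_intron_sites tests
intron_row <- function(gene_id, ordinal, offset, phase = offset %% 3,
                       gstart = 1000L + offset, gend = 1100L + offset,
                       chrom = "chr", sequence = NA_character_) {
  data.frame(gene_id = gene_id, chrom = chrom, ordinal = ordinal,
             cds_offset = offset, phase = phase,
             length = gend - gstart, gstart = gstart, gend = gend,
             sequence = sequence,
             donor2 = NA_character_, acceptor2 = NA_character_)
}

# a coding_alignment built from explicit gapped CDS strings
manual_alignment <- function(cds_a, cds_b, gene_a = "ga", gene_b = "gb") {
  structure(list(gene_a = gene_a, gene_b = gene_b,
                 aligned_protein_a = NULL, aligned_protein_b = NULL,
                 aligned_cds_a = cds_a, aligned_cds_b = cds_b,
                 chars_a = strsplit(cds_a, "", fixed = TRUE)[[1]],
                 chars_b = strsplit(cds_b, "", fixed = TRUE)[[1]]),
            class = "coding_alignment")
}

# in-memory pipeline config for a simulation result
sim_pipeline_config <- function(sim, ...) {
  cfg <- c(list(
    species = lapply(sim$species, function(s)
      list(models = s$models, introns = s$introns,
           junctions = s$junctions)),
    hits = sim$hits, tree = "((((DDB,DPU),PPA),DFA),EHI);",
    focal = c("DDB", "DPU"), run_id = sim$truth$run_id,
    gain_hits = sim$gain_hits, gain_intron_info = sim$gain_intron_info),
    pipeline_options())
  opts <- list(...)
  cfg[names(opts)] <- opts
  cfg
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}
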