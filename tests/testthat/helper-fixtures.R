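# Programmatic fixtures shared across test files.

meta_tbl <- function(ids, tissue = "gonad", genotype = "wild_type",
                     temperature_c = 25, replicate = NULL) {
  tibble::tibble(
    sample_id = ids,
    tissue = rep_len(tissue, length(ids)),
    genotype = rep_len(genotype, length(ids)),
    temperature_c = rep_len(temperature_c, length(ids)),
    replicate = replicate %||% seq_along(ids)
  )
}

make_counts <- function(m, gene_prefix = "g", sample_prefix = "s",
                        tissue = "gonad", genotype = "wild_type") {
  n <- nrow(m)
  ids <- paste0(sample_prefix, seq_len(ncol(m)))
  tab <- tibble::tibble(gene_id = sprintf("%s%03d", gene_prefix, seq_len(n)))
  for (j in seq_len(ncol(m))) tab[[ids[j]]] <- m[, j]
  count_matrix(tab, meta_tbl(ids, tissue = tissue, genotype = genotype))
}

random_counts <- function(n_genes, n_samples, lambda = 50) {
  make_counts(matrix(rpois(n_genes * n_samples, lambda), n_genes, n_samples))
}

rpm_of <- function(vals, ids = sprintf("g%03d", seq_len(nrow(as.matrix(vals)))),
                   unit = "RPM") {
  m <- as.matrix(vals)
  tab <- tibble::tibble(gene_id = ids)
  for (j in seq_len(ncol(m))) tab[[paste0("s", j)]] <- m[, j]
  structure(tab, unit = unit, class = c("abundance_matrix", class(tibble::tibble())))
}

annotation_of <- function(ids, lengths) {
  tibble::tibble(gene_id = ids, length_nt = lengths, biotype = NA_character_)
}

# A 5-gene GTF with known exon structures; expected longest-isoform lengths
# were computed by summing the exon lengths (end - start + 1) per transcript
# by hand below, independently of the reader.
write_fixture_gtf <- function(path) {
  line <- function(gene, tx, start, end) {
    sprintf(paste0("chrI\ttest\texon\t%d\t%d\t.\t+\t.\t",
                   "gene_id \"%s\"; transcript_id \"%s\";"), start, end, gene, tx)
  }
  lines <- c(
    # gA: tx1 = 100 + 50, tx2 = 300  -> 300
    line("gA", "gA.1", 101, 200), line("gA", "gA.1", 301, 350),
    line("gA", "gA.2", 1001, 1300),
    # gB: single exon 101..200 -> 100
    line("gB", "gB.1", 101, 200),
    # gC: tx1 = 500, tx2 = 250 + 550 = 800 -> 800
    line("gC", "gC.1", 1, 500),
    line("gC", "gC.2", 601, 850), line("gC", "gC.2", 901, 1450),
    # gD: overlapping exons in one transcript summed as given: 200 + 200 -> 400
    line("gD", "gD.1", 101, 300), line("gD", "gD.1", 201, 400),
    # gE: three exons 10 + 20 + 30 -> 60
    line("gE", "gE.1", 1, 10), line("gE", "gE.1", 21, 40), line("gE", "gE.1", 61, 90)
  )
  writeLines(lines, path)
  c(gA = 300, gB = 100, gC = 800, gD = 400, gE = 60)
}

# brute-force exon-sum oracle on a GTF file, independent of read_gene_lengths
gtf_length_oracle <- function(path) {
  raw <- readLines(path)
  f <- strsplit(raw, "\t")
  tx_len <- list()
  tx_gene <- list()
  for (row in f) {
    if (row[3] != "exon") next
    at <- row[9]
    gid <- sub('.*gene_id "([^"]+)".*', "\\1", at)
    tid <- sub('.*transcript_id "([^"]+)".*', "\\1", at)
    len <- as.numeric(row[5]) - as.numeric(row[4]) + 1
    tx_len[[tid]] <- (tx_len[[tid]] %||% 0) + len
    tx_gene[[tid]] <- gid
  }
  genes <- unique(unlist(tx_gene))
  sapply(genes, function(g) {
    max(unlist(tx_len[names(tx_gene)[unlist(tx_gene) == g]]))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

two_group_counts <- function(m) {
  n <- ncol(m) / 2
  cm <- make_counts(m)
  meta <- meta_tbl(sample_ids(cm),
                   genotype = rep(c("wild_type", "mutant"), each = n),
                   replicate = rep(seq_len(n), 2))
  cm <- count_matrix(tibble::as_tibble(as.data.frame(cm)), meta)
  list(cm = cm, groups = setNames(meta$genotype, meta$sample_id))
}
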