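seqs3 <- c(tax1 = "ACGTACGTACGT", tax2 = "ACGTACGAACGT",
           tax3 = "ACGTTCGTACGA")

test_that("FASTA and NEXUS parse to the same alignment", {
  fa <- writeFastaFixture(seqs3)
  nx <- writeNexusFixture(seqs3)
  a <- readAlignment(fa, "fasta")
  b <- readAlignment(nx, "nexus")
  expect_equal(nSites(a), 12L)
  expect_equal(taxa(a), names(seqs3))
  expect_identical(as.matrix(a), as.matrix(b))
})

test_that("ragged rows and duplicate labels are rejected", {
  fa <- writeFastaFixture(c(a = "ACGTACGTACGT", b = "ACGTACGTACG"))
  expect_error(readAlignment(fa), "alignment-length")
  fa2 <- writeFastaFixture(c(a = "ACGT", a = "ACGT"))
  expect_error(readAlignment(fa2), "label error")
  expect_error(mitoAlignment(c(x = "ACGT", y = "ACG")),
               "alignment-length")
})

test_that("gene extraction slices, wraps the origin and honours strand", {
  set.seed(42)
  m <- matrix(sample(c("A", "C", "G", "T"), 300, replace = TRUE), 3, 100)
  rownames(m) <- c("s1", "s2", "s3")
  aln <- mitoAlignment(m)

  g <- extractGene(aln, geneAnnotation("plus", 11, 40))
  expect_equal(nSites(g), 30L)
  expect_identical(as.matrix(g)[, 1L], m[, 11L])

  ## wrap through the circular origin: columns 91..100 then 1..10
  w <- extractGene(aln, geneAnnotation("wrap", 91, 10))
  expect_equal(nSites(w), 20L)
  expect_identical(unname(as.matrix(w)),
                   unname(cbind(m[, 91:100], m[, 1:10])))

  ## minus strand: reverse complement; double revcomp restores
  minus <- extractGene(aln, geneAnnotation("m", 11, 40, strand = "-"))
  expect_equal(nSites(minus), 30L)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_identical(unname(as.matrix(minus)[, 1L]),
                   unname(comp[m[, 40L]]))
  twice <- mitoAlignment(as.matrix(minus))
  back <- extractGene(twice, geneAnnotation("b", 1, 30, strand = "-"))
  expect_identical(unname(as.matrix(back)),
                   unname(m[, 11:40]))

  expect_error(extractGene(aln, geneAnnotation("bad", 5, 101)),
               "annotation error")
})

test_that("wrap-around of the whole circle returns every column once", {
  m <- matrix(sample(c("A", "C", "G", "T"), 60, replace = TRUE), 3, 20)
  rownames(m) <- paste0("t", 1:3)
  aln <- mitoAlignment(m)
  full <- extractGene(aln, geneAnnotation("circ", 7, 6))
  expect_equal(nSites(full), 20L)
  expect_identical(unname(as.matrix(full)),
                   unname(m[, c(7:20, 1:6)]))
})

test_that("concatenation appends columns and records one block per part", {
  widths <- c(957L, 1545L, 1378L)
  mk <- function(w) {
    m <- matrix("A", 3, w, dimnames = list(c("x", "y", "z"), NULL))
    mitoAlignment(m)
  }
  parts <- lapply(widths, mk)
  cc <- concatenateGenes(parts, c("g1", "g2", "g3"))
  expect_equal(nSites(cc$alignment), 3880L)
  expect_equal(nBlocks(cc$scheme), 3L)
  expect_equal(lengths(blocks(cc$scheme)), c(g1 = 957L, g2 = 1545L,
                                             g3 = 1378L))
  one <- concatenateGenes(parts[1], "only")
  expect_equal(nSites(one$alignment), 957L)
  expect_equal(nBlocks(one$scheme), 1L)
  bad <- mitoAlignment(matrix("A", 2, 5,
                              dimnames = list(c("p", "q"), NULL)))
  expect_error(concatenateGenes(list(parts[[1]], bad)),
               "concatenation error")
})

test_that("taxa are reordered to the first part's order", {
  a <- mitoAlignment(c(x = "AA", y = "CC"))
  b <- mitoAlignment(c(y = "GG", x = "TT"))
  cc <- concatenateGenes(list(a, b), c("a", "b"))
  expect_equal(taxa(cc$alignment), c("x", "y"))
  expect_equal(paste(as.matrix(cc$alignment)["x", ], collapse = ""),
               "AATT")
})

test_that("codon partitioning assigns positions from the reading frame", {
  m <- matrix("A", 2, 9, dimnames = list(c("u", "v"), NULL))
  aln <- mitoAlignment(m)
  gene <- geneAnnotation("g", 1, 9, coding = TRUE, frame = 0L)
  sch <- codonPartition(aln, gene, "by_codon")
  expect_equal(nBlocks(sch), 3L)
  expect_equal(blocks(sch)$pos1, c(1L, 4L, 7L))
  expect_equal(blocks(sch)$pos2, c(2L, 5L, 8L))
  expect_equal(blocks(sch)$pos3, c(3L, 6L, 9L))
})

test_that("gene-by-codon schemes count 3 blocks per coding gene", {
  m <- matrix("A", 2, 48, dimnames = list(c("u", "v"), NULL))
  aln <- mitoAlignment(m)
  genes <- do.call(rbind, lapply(0:3, function(i)
    geneAnnotation(paste0("g", i + 1), i * 12 + 1, (i + 1) * 12)))
  sch <- codonPartition(aln, genes, "by_gene_and_codon")
  expect_equal(nBlocks(sch), 12L)
  expect_equal(sum(lengths(blocks(sch))), 48L)
  sch3 <- codonPartition(aln, genes[1:3, ], "by_codon")
  expect_equal(nBlocks(sch3), 3L)
  expect_equal(sum(lengths(blocks(sch3))), 36L)
  expect_equal(nBlocks(codonPartition(aln, genes, "by_gene")), 4L)
  expect_equal(nBlocks(codonPartition(aln, genes, "unpartitioned")), 1L)
  nc <- geneAnnotation("rRNA", 1, 12, coding = FALSE)
  expect_error(codonPartition(aln, nc, "by_codon"), "partition error")
})

test_that("overlapping genes keep shared columns in both partitions", {
  m <- matrix("A", 2, 30, dimnames = list(c("u", "v"), NULL))
  aln <- mitoAlignment(m)
  genes <- rbind(geneAnnotation("g1", 1, 18),
                 geneAnnotation("g2", 16, 30))  # 3-site overlap
  sch <- codonPartition(aln, genes, "by_gene_and_codon")
  ## overlap-duplicated sites counted once per gene containing them
  expect_equal(sum(lengths(blocks(sch))), 18L + 15L)
  expect_true(all(16:18 %in% unlist(blocks(sch)[1:3])))
  expect_true(all(16:18 %in% unlist(blocks(sch)[4:6])))
})

test_that("haplotype collapse groups exact string duplicates", {
  s <- c(a = "ACGT", b = "ACGT", c = "ACGA", d = "AC-T", e = "AC-T")
  h <- collapseHaplotypes(mitoAlignment(s))
  expect_equal(h$n_sequences, 5L)
  expect_equal(h$n_unique_haplotypes, 3L)
  expect_equal(unname(h$collapse_map), c(1L, 1L, 2L, 3L, 3L))
  same <- collapseHaplotypes(mitoAlignment(
    setNames(rep("AAAA", 5), paste0("t", 1:5))))
  expect_equal(same$n_unique_haplotypes, 1L)
  dist5 <- collapseHaplotypes(mitoAlignment(
    setNames(c("AAAA", "AAAC", "AACC", "ACCC", "CCCC"),
             paste0("t", 1:5))))
  expect_equal(dist5$n_unique_haplotypes, 5L)
})

test_that("a sub-alignment never gains haplotypes", {
  set.seed(7)
  for (rep in 1:5) {
    m <- matrix(sample(c("A", "C", "G", "T"), 10 * 60, replace = TRUE),
                10, 60, dimnames = list(paste0("t", 1:10), NULL))
    aln <- mitoAlignment(m)
    full <- collapseHaplotypes(aln)$n_unique_haplotypes
    sub <- extractGene(aln, geneAnnotation("g", 11, 30))
    expect_lte(collapseHaplotypes(sub)$n_unique_haplotypes, full)
  }
})

test_that("partition schemes round-trip to RAxML-style text", {
  m <- matrix("A", 2, 9, dimnames = list(c("u", "v"), NULL))
  sch <- codonPartition(mitoAlignment(m),
                        geneAnnotation("g", 1, 9), "by_codon")
  path <- tempfile()
  writePartitionScheme(sch, path)
  lines <- readLines(path)
  expect_equal(length(lines), 3L)
  expect_match(lines[1], "^DNA, pos1 = 1-7\\\\3$")
})
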