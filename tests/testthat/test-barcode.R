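test_that("FASTA I/O round-trips with species labels and rejects bad input", {
  bc <- simulate_barcode_set(seed = 5)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(bc, path)
  expect_identical(read_fasta(path), bc)

  # lowercase sequences are uppercased on read
  writeLines(c(">a species=vagans", "acgtacgt", ">b", "ACGTACGA"), path)
  rec <- read_fasta(path)
  expect_equal(rec$sequence[1], "ACGTACGT")
  expect_equal(rec$species, c("vagans", "unknown"))

  writeLines(c(">a", "ACGT", ">a", "ACGA"), path)
  expect_error(read_fasta(path), "duplicate")
  writeLines(character(0), path)
  expect_error(read_fasta(path), "empty")
  expect_error(read_fasta(file.path(tempdir(), "nope.fasta")), "not found")
})

test_that("haplotype collapse partitions the input deterministically and idempotently", {
  bc <- simulate_barcode_set(seed = 6)
  h <- collapse_haplotypes(bc)
  expect_s3_class(h, "haplotype_set")
  expect_length(h, 4)
  # member counts conserve the input sequence count
  expect_equal(sum(vapply(h, `[[`, integer(1), "size")), nrow(bc))
  expect_setequal(unlist(lapply(h, `[[`, "member_ids")), bc$id)
  # all members of a haplotype share its sequence
  for (hp in h) {
    expect_true(all(bc$sequence[bc$id %in% hp$member_ids] == hp$sequence))
  }
  # idempotence: collapsing the representatives yields one haplotype each
  reps <- data.frame(id = vapply(h, `[[`, character(1), "haplotype"),
                     species = "unknown",
                     sequence = vapply(h, `[[`, character(1), "sequence"))
  h2 <- collapse_haplotypes(reps)
  expect_length(h2, length(h))
  expect_equal(vapply(h2, `[[`, character(1), "sequence"),
               vapply(h, `[[`, character(1), "sequence"))

  same <- data.frame(id = c("x", "y"), species = "vagans",
                     sequence = rep("ACGTACGT", 2))
  expect_length(collapse_haplotypes(same), 1)
  uneq <- data.frame(id = c("x", "y"), species = "vagans",
                     sequence = c("ACGT", "ACGTA"))
  expect_error(collapse_haplotypes(uneq), "unequal length")
})

test_that("percent identity is a symmetric closed-form Hamming similarity", {
  a <- strrep("ACGT", 35)  # 140-mer
  b_chars <- strsplit(a, "")[[1]]
  swap <- c(3, 17, 40, 77, 101, 139)
  b_chars[swap] <- c("T", "G", "A", "C", "T", "C")
  b <- paste(b_chars, collapse = "")
  expect_equal(percent_identity(a, b), 1 - 6 / 140)
  expect_equal(percent_identity(b, a), percent_identity(a, b))
  expect_equal(percent_identity(a, a), 1.0)

  # ambiguity codes are excluded from both numerator and denominator
  a2 <- "ACGTACGTAC"
  b2 <- "ACGNACGTAY"  # 2 ambiguous sites, 8 comparable, all matching
  expect_equal(percent_identity(a2, b2), 1.0)
  b3 <- "ATGNACGTAY"
  expect_equal(percent_identity(a2, b3), 7 / 8)
  expect_error(percent_identity("NNN", "ACG"), "comparable")
  expect_error(percent_identity("ACGT", "ACG"), "unequal length")

  # 1 - identity obeys the triangle inequality on constructed triples
  set.seed(81)
  for (rep in 1:20) {
    base <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    mut <- function(s, k) {
      ch <- strsplit(s, "")[[1]]
      pos <- sample(60, k)
      ch[pos] <- vapply(ch[pos],
                        function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1),
                        character(1))
      paste(ch, collapse = "")
    }
    x <- mut(base, sample(10, 1)); y <- mut(base, sample(10, 1))
    dxb <- 1 - percent_identity(x, base)
    dyb <- 1 - percent_identity(y, base)
    dxy <- 1 - percent_identity(x, y)
    expect_lte(dxy, dxb + dyb + 1e-12)
  }
})

test_that("group similarity reproduces the constructed divergences", {
  bc <- simulate_barcode_set(seed = 7)
  gs <- group_similarity(bc)
  expect_equal(gs["sandersoni", "vagans"], 1 - 6 / 140)
  expect_equal(round(100 * gs["sandersoni", "vagans"], 1), 95.7)
  # monomorphic species are 100% similar within
  expect_equal(gs["sandersoni", "sandersoni"], 1.0)
  expect_equal(gs["vagans", "vagans"], 1.0)
  # the split species is slightly below 1 within: exact pair-count average
  n <- 22; k <- 11
  expected_within <- 1 - (k * (n - k)) / choose(n, 2) / 140
  expect_equal(gs["perplexus", "perplexus"], expected_within, tolerance = 1e-12)
  expect_true(isSymmetric(gs))

  # single-member groups get NA within-group identity
  two <- data.frame(id = c("a", "b"), species = c("s1", "s2"),
                    sequence = c("ACGT", "ACGA"))
  gs2 <- group_similarity(two)
  expect_true(is.na(gs2["s1", "s1"]))
  expect_equal(gs2["s1", "s2"], 0.75)
})

test_that("the haplotype network is a deterministic minimum-spanning forest", {
  bc <- simulate_barcode_set(seed = 8)
  h <- collapse_haplotypes(bc)
  net <- build_network(h, connection_limit = 10)
  # forest property: edges = nodes - components
  expect_equal(nrow(net$edges), nrow(net$nodes) - max(net$components))
  # the two perplexus haplotypes are joined by a single 1 bp edge
  perp <- vapply(h, function(x) "perplexus" %in% names(x$species), logical(1))
  perp_ids <- vapply(h[perp], `[[`, character(1), "haplotype")
  e11 <- net$edges[net$edges$from %in% perp_ids & net$edges$to %in% perp_ids, ]
  expect_equal(nrow(e11), 1L)
  expect_equal(e11$n_diff, 1L)
  # node sizes conserve the sequence count
  expect_equal(sum(net$nodes$size), nrow(bc))

  # limit 0 disconnects everything
  net0 <- build_network(h, connection_limit = 0)
  expect_equal(nrow(net0$edges), 0L)
  expect_equal(max(net0$components), length(h))

  # a limit below the interspecific divergence separates the species groups,
  # keeping only the intraspecific connection
  net5 <- build_network(h, connection_limit = 5)
  expect_equal(max(net5$components), 3L)
  expect_equal(nrow(net5$edges), 1L)
  expect_equal(net5$edges$n_diff, 1L)

  expect_identical(build_network(h, 10), build_network(h, 10))
})
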