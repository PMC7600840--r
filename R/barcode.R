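#' Read an aligned barcode FASTA file
#'
#' Reads DNA sequences via [Biostrings::readDNAStringSet()]. The record id
#' is the first whitespace-separated token of the FASTA header; a
#' `species=<name>` token anywhere in the description, when present, sets
#' the species label (otherwise `unknown`). Sequences are uppercased;
#' length consistency is checked by the analysis operations, not here.
#'
#' @param path FASTA file path.
#' @return data frame with `id`, `species`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(ss)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  species <- vapply(headers, function(h) {
    m <- regmatches(h, regexpr("species=[^\\s]+", h, perl = TRUE))
    if (length(m)) sub("^species=", "", m) else "unknown"
  }, character(1), USE.NAMES = FALSE)
  data.frame(id = ids, species = species,
             sequence = unname(toupper(as.character(ss))),
             stringsAsFactors = FALSE)
}

#' Write a barcode set to FASTA
#'
#' Inverse of [read_fasta()]: headers are `<id> species=<species>`.
#'
#' @param records data frame with `id`, `species`, `sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  ss <- Biostrings::DNAStringSet(records$sequence)
  names(ss) <- paste0(records$id, " species=", records$species)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

.check_aligned <- function(sequences) {
  L <- unique(nchar(sequences))
  if (length(L) != 1L) {
    stop("sequences have unequal lengths (", paste(L, collapse = ", "),
         "); an ungapped alignment is required", call. = FALSE)
  }
  L
}

#' Collapse aligned sequences into haplotypes
#'
#' One haplotype per distinct sequence. Haplotypes are named `H1`, `H2`,
#' ... in order of first appearance in the input (deterministic), and carry
#' their member ids and species composition. Collapsing is idempotent and
#' conserves the input count: haplotype sizes sum to the number of input
#' sequences.
#'
#' @param records data frame with `id`, `species`, `sequence` (all
#'   sequences the same length).
#' @return list of class `haplotype_set`; each element has `haplotype`,
#'   `sequence`, `size`, `member_ids`, `species` (a named table).
#' @export
collapse_haplotypes <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  .check_aligned(records$sequence)
  useq <- unique(records$sequence)
  out <- lapply(seq_along(useq), function(i) {
    members <- which(records$sequence == useq[i])
    list(haplotype = sprintf("H%d", i),
         sequence = useq[i],
         size = length(members),
         member_ids = records$id[members],
         species = table(records$species[members]))
  })
  class(out) <- "haplotype_set"
  out
}

# Character matrix (sequences x sites) for vectorized comparisons.
.char_matrix <- function(sequences) {
  do.call(rbind, strsplit(sequences, "", fixed = TRUE))
}

#' Percent identity between two aligned sequences
#'
#' Fraction of matching sites among comparable sites. Sites where either
#' sequence carries a non-ACGT symbol (N, IUPAC ambiguity codes, gaps) are
#' excluded from both numerator and denominator, so ambiguity never counts
#' as either match or mismatch. Symmetric in its arguments; `1 - identity`
#' is the normalised Hamming distance.
#'
#' @param a,b equal-length sequence strings (or one-row data frames with a
#'   `sequence` column).
#' @return proportion in \[0, 1\].
#' @export
percent_identity <- function(a, b) {
  if (is.data.frame(a)) a <- a$sequence
  if (is.data.frame(b)) b <- b$sequence
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  .check_aligned(c(a, b))
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  acgt <- c("A", "C", "G", "T")
  comparable <- ca %in% acgt & cb %in% acgt
  if (!any(comparable)) stop("no comparable (unambiguous) sites", call. = FALSE)
  sum(ca[comparable] == cb[comparable]) / sum(comparable)
}

#' Mean within- and between-species percent identity
#'
#' Mean pairwise identity over all unordered pairs of individuals, within
#' each species (diagonal; `NA` for species with a single member) and
#' between each species pair (off-diagonal).
#'
#' @param records data frame with `id`, `species`, `sequence` (aligned).
#' @return symmetric numeric matrix, species x species.
#' @export
group_similarity <- function(records) {
  stopifnot(is.data.frame(records))
  species <- sort(unique(records$species))
  if (length(species) < 2L) stop("need >= 2 species", call. = FALSE)
  .check_aligned(records$sequence)
  cm <- .char_matrix(toupper(records$sequence))
  ok <- cm %in% c("A", "C", "G", "T")
  dim(ok) <- dim(cm)
  n <- nrow(cm)
  pid <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      pid[i, j] <- pid[j, i] <- sum(cm[i, comp] == cm[j, comp]) / sum(comp)
    }
  }
  out <- matrix(NA_real_, length(species), length(species),
                dimnames = list(species, species))
  for (a in seq_along(species)) {
    for (b in a:length(species)) {
      ia <- which(records$species == species[a])
      ib <- which(records$species == species[b])
      if (a == b) {
        if (length(ia) >= 2L) {
          sub <- pid[ia, ia, drop = FALSE]
          out[a, a] <- mean(sub[upper.tri(sub)])
        }
      } else {
        out[a, b] <- out[b, a] <- mean(pid[ia, ib])
      }
    }
  }
  out
}

#' Haplotype network by minimum-spanning forest
#'
#' Builds a parsimony-style haplotype network: nodes are haplotypes, edge
#' weights are pairwise base-pair differences between representative
#' sequences, and the network is the minimum-spanning forest (Kruskal's
#' algorithm) over the graph restricted to pairs differing by at most
#' `connection_limit` substitutions. Ties between equal-weight edges are
#' broken deterministically by haplotype order, so the network is
#' reproducible. Haplotype groups more divergent than the limit stay
#' disconnected, which is how distinct species separate into components.
#'
#' This is a simplification of full statistical-parsimony network
#' estimation: the probabilistic connection-limit calculation is replaced
#' by an explicit substitution-step limit (default 10 steps, a typical
#' parsimony limit for a fragment of ~150 bp).
#'
#' @param haplotypes a [collapse_haplotypes()] result.
#' @param connection_limit maximum substitution steps for an edge
#'   (default 10).
#' @return list of class `haplotype_network` with `nodes` (data frame:
#'   `haplotype`, `size`, `species`), `edges` (data frame: `from`, `to`,
#'   `n_diff`), `components` (named membership vector) and
#'   `connection_limit`.
#' @export
build_network <- function(haplotypes, connection_limit = 10L) {
  stopifnot(inherits(haplotypes, "haplotype_set"), length(haplotypes) >= 1L)
  k <- length(haplotypes)
  names_h <- vapply(haplotypes, `[[`, character(1), "haplotype")
  seqs <- vapply(haplotypes, `[[`, character(1), "sequence")
  .check_aligned(seqs)
  cm <- .char_matrix(seqs)

  edges <- data.frame(from = integer(0), to = integer(0), n_diff = integer(0))
  if (k >= 2L) {
    pairs <- utils::combn(k, 2)
    n_diff <- apply(pairs, 2, function(ij) sum(cm[ij[1], ] != cm[ij[2], ]))
    edges <- data.frame(from = pairs[1, ], to = pairs[2, ], n_diff = n_diff)
    edges <- edges[edges$n_diff <= connection_limit, , drop = FALSE]
    edges <- edges[order(edges$n_diff, edges$from, edges$to), , drop = FALSE]
  }

  # Kruskal with union-find
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  keep <- logical(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    ra <- find(edges$from[e]); rb <- find(edges$to[e])
    if (ra != rb) { parent[ra] <- rb; keep[e] <- TRUE }
  }
  edges <- edges[keep, , drop = FALSE]

  comp_root <- vapply(seq_len(k), find, integer(1))
  components <- setNames(match(comp_root, unique(comp_root)), names_h)
  nodes <- data.frame(
    haplotype = names_h,
    size = vapply(haplotypes, `[[`, integer(1), "size"),
    species = vapply(haplotypes, function(h) {
      paste(sprintf("%s:%d", names(h$species), as.integer(h$species)),
            collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE)
  out_edges <- data.frame(from = names_h[edges$from], to = names_h[edges$to],
                          n_diff = as.integer(edges$n_diff),
                          stringsAsFactors = FALSE)
  rownames(out_edges) <- NULL
  structure(list(nodes = nodes, edges = out_edges, components = components,
                 connection_limit = as.integer(connection_limit)),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("Haplotype network: %d haplotypes, %d edges, %d component(s), limit %d bp\n",
              nrow(x$nodes), nrow(x$edges), max(x$components),
              x$connection_limit))
  invisible(x)
}
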