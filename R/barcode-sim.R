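#' Specification for a synthetic barcode set
#'
#' Defines the construction of a toy aligned COI barcode fragment set with
#' exact pairwise divergences. Species templates of common length are built
#' from one random backbone by substituting bases at disjoint or shared site
#' sets so that the Hamming distances between the three species templates
#' equal the requested divergences exactly; optionally one species is split
#' into two haplotypes one substitution apart.
#'
#' The default is the package's calibration for this species complex: a
#' 140 bp fragment with 6 substitutions between *B. sandersoni* and
#' *B. vagans* (pairwise identity 1 - 6/140 = 95.7%) and 8 substitutions
#' between *B. perplexus* and each of the other two (1 - 8/140 = 94.3%),
#' with *B. perplexus* split into two haplotypes differing at one site.
#'
#' @param length fragment length in bp.
#' @param divergence named integer vector with elements
#'   `sandersoni.vagans`, `perplexus.sandersoni`, `perplexus.vagans`: target
#'   Hamming distances between species templates.
#' @param haplotype_split `NULL`, or a list with `species` and `freq`: the
#'   species carrying a 1 bp within-species variant and the fraction of its
#'   individuals carrying it.
#' @return a list of class `barcode_sim_spec`.
#' @export
barcode_sim_spec <- function(length = 140L,
                             divergence = c(sandersoni.vagans = 6L,
                                            perplexus.sandersoni = 8L,
                                            perplexus.vagans = 8L),
                             haplotype_split = list(species = "perplexus",
                                                    freq = 0.5)) {
  need <- c("sandersoni.vagans", "perplexus.sandersoni", "perplexus.vagans")
  stopifnot(length >= 1L, all(need %in% names(divergence)),
            all(divergence >= 0))
  structure(list(length = as.integer(length),
                 divergence = divergence[need],
                 haplotype_split = haplotype_split),
            class = "barcode_sim_spec")
}

#' Simulate an aligned barcode fragment set
#'
#' Generates one sequence per individual according to a
#' [barcode_sim_spec()]. Within-species sequences are identical
#' (monomorphic) except for the optional 1 bp haplotype split; pairwise
#' between-species template distances equal the divergence specification
#' exactly. Identical seeds give byte-identical output.
#'
#' The construction places `d(p,s)` substitutions on the sandersoni
#' template and `d(p,v)` on the vagans template relative to the perplexus
#' backbone, sharing `c = (d(p,s) + d(p,v) - d(s,v)) / 2` sites with the
#' *same* substituted base (so those sites do not separate sandersoni from
#' vagans). If the parity of the divergence triangle requires it, one shared
#' site instead carries *different* substituted bases in the two species.
#' An infeasible triangle (violating the triangle inequality or exceeding
#' the fragment length) is an error.
#'
#' @param spec a [barcode_sim_spec()].
#' @param counts named integer vector of individuals per species; the
#'   default (49 sandersoni, 44 vagans, 22 perplexus) reproduces the size
#'   and composition of the DNA-confirmed study sample the calibration
#'   emulates (115 sequences).
#' @param seed integer seed.
#' @return data frame with columns `id`, `species`, `sequence`.
#' @export
simulate_barcode_set <- function(spec = barcode_sim_spec(),
                                 counts = c(sandersoni = 49L, vagans = 44L,
                                            perplexus = 22L),
                                 seed) {
  if (missing(seed)) stop("'seed' is required for reproducibility", call. = FALSE)
  stopifnot(inherits(spec, "barcode_sim_spec"),
            all(.bombus_species %in% names(counts)))
  L <- spec$length
  d_sv <- spec$divergence[["sandersoni.vagans"]]
  d_ps <- spec$divergence[["perplexus.sandersoni"]]
  d_pv <- spec$divergence[["perplexus.vagans"]]
  if (d_sv > d_ps + d_pv || d_ps > d_sv + d_pv || d_pv > d_sv + d_ps) {
    stop("impossible divergence triangle", call. = FALSE)
  }
  # Shared substitution sites between the sandersoni and vagans branches:
  # c2 sites get the same base in both, c3 (0 or 1, for parity) different ones.
  tot <- d_ps + d_pv - d_sv
  c3 <- tot %% 2L
  c2 <- (tot - c3) %/% 2L
  n_sites <- d_ps + d_pv - c2 - c3 + ifelse(is.null(spec$haplotype_split), 0L, 1L)
  if (n_sites > L) stop("fragment too short for requested divergences", call. = FALSE)

  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  backbone <- sample(bases, L, replace = TRUE)  # = perplexus template
  sites <- sample.int(L, n_sites)
  i <- 0L
  take <- function(k) { on.exit(i <<- i + k, add = TRUE); sites[seq_len(k) + i] }
  shared_same <- take(c2)
  shared_diff <- take(c3)
  s_only <- take(d_ps - c2 - c3)
  v_only <- take(d_pv - c2 - c3)
  split_site <- if (is.null(spec$haplotype_split)) integer(0) else take(1L)

  mutate <- function(seq, pos, avoid = NULL) {
    for (p in pos) {
      choices <- setdiff(bases, c(seq[p], avoid[[as.character(p)]]))
      seq[p] <- sample(choices, 1L)
    }
    seq
  }
  sand <- mutate(backbone, c(shared_same, shared_diff, s_only))
  vag <- backbone
  vag[shared_same] <- sand[shared_same]
  avoid <- setNames(as.list(sand[shared_diff]), as.character(shared_diff))
  vag <- mutate(vag, c(shared_diff, v_only), avoid = avoid)

  templates <- list(perplexus = backbone, sandersoni = sand, vagans = vag)
  variant <- NULL
  if (!is.null(spec$haplotype_split)) {
    variant <- mutate(templates[[spec$haplotype_split$species]], split_site)
  }

  blocks <- lapply(names(counts), function(sp) {
    n <- counts[[sp]]
    seqs <- rep(paste(templates[[sp]], collapse = ""), n)
    if (!is.null(variant) && sp == spec$haplotype_split$species) {
      k <- round(spec$haplotype_split$freq * n)
      if (k > 0) seqs[seq_len(k)] <- paste(variant, collapse = "")
    }
    data.frame(id = sprintf("%s_%03d", sp, seq_len(n)), species = sp,
               sequence = seqs, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(blocks, list(make.row.names = FALSE)))
}
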