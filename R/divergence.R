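#' Read a pre-aligned FASTA file
#'
#' @param file path to an aligned nucleotide FASTA.
#' @return named list of upper-case character vectors (one per sequence).
#' @export
read_alignment <- function(file) {
  if (!file.exists(file)) stopf("FASTA file not found: %s", file)
  dna <- ape::read.FASTA(file)
  seqs <- lapply(as.character(dna), function(s) toupper(as.vector(s)))
  names(seqs) <- names(dna)
  seqs
}

#' Uncorrected percent divergence between two aligned sequences
#'
#' p-distance times 100, computed over comparable sites only: positions
#' where both sequences carry an unambiguous A/C/G/T. Gaps and IUPAC
#' ambiguity codes are excluded from numerator and denominator. No
#' multiple-hit correction is applied.
#'
#' @param seq1,seq2 character vectors of equal length (single characters),
#'   or single strings.
#' @param min_sites minimum number of comparable sites for a reported
#'   distance.
#' @return percent divergence (0–100).
#' @examples
#' percent_divergence("ACGTACGTAA", "ACGTACGTAT", min_sites = 10)
#' @export
percent_divergence <- function(seq1, seq2, min_sites = 100) {
  s1 <- prep_seq(seq1); s2 <- prep_seq(seq2)
  if (length(s1) != length(s2))
    stopf("sequences differ in length (%d vs %d)", length(s1), length(s2))
  ok <- s1 %in% c("A", "C", "G", "T") & s2 %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n < min_sites)
    stopf("only %d comparable sites (need >= %d)", n, min_sites)
  100 * sum(s1[ok] != s2[ok]) / n
}

prep_seq <- function(s) {
  if (length(s) == 1L && nchar(s) > 1L) s <- strsplit(s, "")[[1L]]
  toupper(as.character(s))
}

#' Average between-species percent divergence
#'
#' For species represented by multiple sequences, the species-pair distance
#' is the equal-weight average of [percent_divergence()] over all
#' between-species sequence pairs.
#'
#' @param seqs named list of aligned sequences (see [read_alignment()]).
#' @param species_map named character vector mapping sequence name to
#'   species.
#' @param species_pair the two species to compare; default the first two in
#'   `species_map`.
#' @param min_sites per-pair comparable-site requirement.
#' @return average percent divergence.
#' @export
mean_percent_divergence <- function(seqs, species_map,
                                    species_pair = NULL, min_sites = 100) {
  if (is.null(names(species_map))) stopf("species_map must be named")
  sp <- species_pair %||% unique(unname(species_map))[1:2]
  if (length(sp) != 2L || anyNA(sp)) stopf("need exactly two species")
  a <- names(species_map)[species_map == sp[1L]]
  b <- names(species_map)[species_map == sp[2L]]
  if (!length(a) || !length(b))
    stopf("no sequences for species: %s",
          paste(sp[c(!length(a), !length(b))], collapse = ", "))
  miss <- setdiff(c(a, b), names(seqs))
  if (length(miss)) stopf("sequences missing from alignment: %s",
                          paste(miss, collapse = ", "))
  d <- outer(a, b, Vectorize(function(i, j)
    percent_divergence(seqs[[i]], seqs[[j]], min_sites = min_sites)))
  mean(d)
}

#' Molecular-clock conversion of percent divergence to time
#'
#' Divides percent divergence by a clock rate in percent per MY; the
#' default 2.3%/MY is the standard arthropod mitochondrial COI rate.
#' The reported time is rounded to two decimals; the unrounded value is
#' retained in the returned object.
#'
#' @param d percent sequence divergence (>= 0).
#' @param rate clock rate in % per MY (> 0).
#' @return a `clock_estimate`: list with `percent_divergence`, `rate`,
#'   `time_mya` (unrounded) and `time_reported` (2 decimals).
#' @examples
#' divergence_time(5.45)         # 2.37 MY
#' divergence_time(5.71, 2.3)    # 2.48 MY
#' @export
divergence_time <- function(d, rate = 2.3) {
  if (!is.finite(d) || d < 0) stopf("d must be >= 0")
  if (!is.finite(rate) || rate <= 0) stopf("rate must be > 0")
  t <- d / rate
  structure(list(percent_divergence = d, rate = rate,
                 time_mya = t, time_reported = round(t, 2)),
            class = "clock_estimate")
}

#' @export
print.clock_estimate <- function(x, ...) {
  cat(sprintf("%.2f%% divergence at %.3g%%/MY: %.2f MY\n",
              x$percent_divergence, x$rate, x$time_reported))
  invisible(x)
}
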