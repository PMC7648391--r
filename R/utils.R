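# Shared helpers: seeded evaluation, sequence basics, N50.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded package
#' operations never perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible child seed from a run seed and a stage name
#'
#' One top-level seed feeds every stage of a run; each stage draws its own
#' child seed keyed by a stable name, so adding a stage never perturbs the
#' random streams of unrelated stages.
#'
#' @param seed integer run seed.
#' @param stage character stage name.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' stage_seed(42, "simulate_sr")
stage_seed <- function(seed, stage) {
  bytes <- utf8ToInt(paste0(stage, ":", as.integer(seed)))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483629
  as.integer(h %% 2147483561L + 1L)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' N50 of a set of lengths
#'
#' Length at which the cumulative sum of the descending-sorted lengths
#' reaches half of the total.
#'
#' @param lengths numeric vector of sequence lengths.
#' @return the N50 (0 for an empty set).
#' @export
calc_n50 <- function(lengths) {
  lengths <- sort(as.numeric(lengths), decreasing = TRUE)
  if (length(lengths) == 0 || sum(lengths) == 0) return(0)
  cum <- cumsum(lengths)
  lengths[which(cum >= sum(lengths) / 2)[1]]
}

#' GC fraction of DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return overall fraction of G+C over all sequences.
#' @export
gc_fraction <- function(x) {
  if (length(x) == 0) return(NA_real_)
  counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(x))[, c("A", "C", "G", "T"), drop = FALSE])
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  unname((counts["C"] + counts["G"]) / tot)
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
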