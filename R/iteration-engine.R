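# The iterative hybrid assembly loop: subsample -> assemble -> bin ->
# assess -> gate -> deplete -> repeat.  Cycle c MAGs are named H{c}_*;
# depletion always runs against the cumulative qualified MAG set, and the
# loop stops at max_cycles, on a cycle with no newly qualified MAGs, or on
# an empty residual pool.

#' Configuration of an iterative hybrid assembly run
#'
#' Defaults reproduce the reference workflow's proportions (6 Gbp SR and
#' 22 Gbp LR in cycle 1; 20 million pairs and 1 million long reads in later
#' cycles) scaled by `scale` so desk-scale runs keep the same shape.
#'
#' @param scale scale factor applied to the reference cycle sizes.
#' @param cycle1_sr_bp,cycle1_lr_bp cycle-1 subsample sizes in bases.
#' @param later_sr_pairs,later_lr_reads later-cycle subsample sizes.
#' @param max_cycles maximum number of cycles (>= 1).
#' @param gate qualified-MAG gate tier, `"HQ"` (default) or `"DQ"`;
#'   high contiguity is always required.
#' @param seed run seed; every stage derives its own child seed from it.
#' @param k,min_depth,min_contig_len,min_links built-in assembler settings.
#' @param bin_max_clusters,bin_threshold binning settings.
#' @param refine_completeness,refine_contamination bin-refinement gate.
#' @return an `iha_config` list.
#' @export
iha_config <- function(scale = 1e-3,
                       cycle1_sr_bp = 6e9 * scale,
                       cycle1_lr_bp = 22e9 * scale,
                       later_sr_pairs = round(20e6 * scale),
                       later_lr_reads = round(1e6 * scale),
                       max_cycles = 5, gate = "HQ", seed = 1,
                       k = 31, min_depth = 3, min_contig_len = 1000,
                       min_links = 2, bin_max_clusters = 24,
                       bin_threshold = 0.15,
                       refine_completeness = 70,
                       refine_contamination = 10) {
  stopifnot(max_cycles >= 1, cycle1_sr_bp > 0, cycle1_lr_bp > 0,
            later_sr_pairs > 0, later_lr_reads > 0)
  cfg <- list(cycle1_sr_bp = cycle1_sr_bp, cycle1_lr_bp = cycle1_lr_bp,
              later_sr_pairs = later_sr_pairs,
              later_lr_reads = later_lr_reads,
              max_cycles = as.integer(max_cycles), gate = gate,
              seed = as.integer(seed), k = k, min_depth = min_depth,
              min_contig_len = min_contig_len, min_links = min_links,
              bin_max_clusters = bin_max_clusters,
              bin_threshold = bin_threshold,
              refine_completeness = refine_completeness,
              refine_contamination = refine_contamination)
  class(cfg) <- "iha_config"
  cfg
}

#' Run one cycle of the iterative loop
#'
#' @param state run state from [iha_init()] or a previous cycle.
#' @param config an [iha_config()].
#' @param lib the [marker_library()] used for quality assessment.
#' @return the updated state.
#' @export
run_cycle <- function(state, config, lib) {
  cyc <- state$cycle + 1L
  if (nrow(state$pairs) == 0)
    stop("residual short-read pool is empty; run ends")
  sseed <- function(tag) stage_seed(config$seed, sprintf("c%d_%s", cyc, tag))
  if (cyc == 1L) {
    sub_pairs <- subsample_pairs(state$pairs, total_bp = config$cycle1_sr_bp,
                                 seed = sseed("sr"))
    sub_long <- subsample_long(state$long, total_bp = config$cycle1_lr_bp,
                               seed = sseed("lr"))
  } else {
    sub_pairs <- subsample_pairs(state$pairs,
                                 n_pairs = config$later_sr_pairs,
                                 seed = sseed("sr"))
    sub_long <- subsample_long(state$long, n_reads = config$later_lr_reads,
                               seed = sseed("lr"))
  }
  contigs <- toy_hybrid_assemble(sub_pairs, sub_long, k = config$k,
                                 min_depth = config$min_depth,
                                 min_contig_len = config$min_contig_len,
                                 min_links = config$min_links)
  mags <- list()
  n_bins <- 0L
  if (nrow(contigs) > 0) {
    binned <- toy_bin(contigs, max_clusters = config$bin_max_clusters,
                      threshold = config$bin_threshold)
    n_bins <- length(binned$bins)
    refined <- refine_bins(binned$bins, lib,
                           min_completeness = config$refine_completeness,
                           max_contamination = config$refine_contamination)
    for (bi in seq_along(refined$bins)) {
      b <- refined$bins[[bi]]
      qa <- assess_bin(b$contigs, lib)
      mag_id <- sprintf("H%d_B%02d", cyc, bi)
      mags[[length(mags) + 1]] <-
        list(mag_id = mag_id, contigs = b$contigs, qa = qa)
    }
  }
  qualified_new <- Filter(function(m) is_qualified(m$qa, config$gate), mags)
  state$qualified <- c(state$qualified, qualified_new)
  state$last_cycle_mags <- mags

  # depletion against ALL accumulated qualified MAGs
  if (length(state$qualified) > 0) {
    mag_seqs <- unlist(lapply(state$qualified, function(m) m$contigs$seq))
    srp <- recruit_short(state$pairs, mag_seqs)
    lrp <- recruit_long(state$long, mag_seqs)
    pools <- cycle_pools(srp, lrp, nrow(state$pairs), nrow(state$long))
    dep <- deplete(pools)
  } else {
    dep <- list(residual_pairs = state$pairs, residual_long = state$long,
                report = NULL)
  }
  state$log[[cyc]] <- data.frame(
    cycle = cyc,
    pairs_in = nrow(state$pairs), long_in = nrow(state$long),
    pairs_sub = nrow(sub_pairs), long_sub = nrow(sub_long),
    n_contigs = nrow(contigs), n_bins = n_bins,
    mags_found = length(mags), mags_qualified = length(qualified_new),
    pairs_residual = nrow(dep$residual_pairs),
    long_residual = nrow(dep$residual_long),
    stringsAsFactors = FALSE)
  state$pairs <- dep$residual_pairs
  state$long <- dep$residual_long
  state$cycle <- cyc
  state$new_qualified <- length(qualified_new)
  state
}

#' Initialize the run state
#' @param pairs short-read `pair_set` (the full pool).
#' @param long_reads long-read `seq_set`.
#' @return a fresh run state.
#' @export
iha_init <- function(pairs, long_reads) {
  list(cycle = 0L, pairs = pairs, long = long_reads,
       qualified = list(), last_cycle_mags = list(), log = list(),
       new_qualified = NA_integer_)
}

#' Run the full iterative hybrid assembly loop
#'
#' Cycles run until `max_cycles` is reached, a cycle yields no newly
#' qualified MAGs, or the residual pools are exhausted.  The final MAG set
#' is the accumulated qualified MAGs plus the last cycle's non-qualified
#' MAGs of at least draft quality, dereplicated by MinHash distance.
#'
#' @param pairs short-read `pair_set`.
#' @param long_reads long-read `seq_set`.
#' @param config an [iha_config()].
#' @param lib a [marker_library()].
#' @param dereplicate_distance MinHash distance for final dereplication.
#' @param on_cycle optional callback `function(state)` invoked after every
#'   cycle (e.g. to record truth-resolved pool compositions).
#' @return list with `mags` (final MAG records), `manifest` (data frame),
#'   `log` (per-cycle data frame) and `state` (final run state).
#' @export
run_iha <- function(pairs, long_reads, config, lib,
                    dereplicate_distance = 0.05, on_cycle = NULL) {
  state <- iha_init(pairs, long_reads)
  for (cyc in seq_len(config$max_cycles)) {
    if (nrow(state$pairs) == 0) break
    state <- run_cycle(state, config, lib)
    if (!is.null(on_cycle)) on_cycle(state)
    if (state$new_qualified == 0) break
    if (nrow(state$pairs) == 0) break
  }
  final <- state$qualified
  qual_ids <- vapply(final, function(m) m$mag_id, character(1))
  for (m in state$last_cycle_mags) {
    if (m$mag_id %in% qual_ids) next
    if (m$qa$tier %in% c("FINISHED", "HQ", "DQ"))
      final[[length(final) + 1]] <- m
  }
  if (length(final) > 1)
    final <- dereplicate(final, max_distance = dereplicate_distance)
  manifest <- do.call(rbind, lapply(final, function(m)
    manifest_row(m$mag_id, m$qa)))
  log <- if (length(state$log)) do.call(rbind, state$log) else NULL
  list(mags = final, manifest = manifest, log = log, state = state)
}

#' Normalize a mean depth to coverage per 10 Gbp
#'
#' @param depth mean read depth of a MAG in one read class.
#' @param class_total_bp total sequenced bases of that read class.
#' @return coverage the MAG would have had at exactly 10 Gbp of that class.
#' @export
#' @examples
#' normalized_coverage(4.5, 30e9) # 1.5
normalized_coverage <- function(depth, class_total_bp) {
  stopifnot(all(class_total_bp > 0))
  depth * 1e10 / class_total_bp
}
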