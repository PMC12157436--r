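#' Diffraction limit used as the detection-matching radius
#'
#' Abbe resolution `lambda / (2 NA)` in nm. The matching radius of
#' [detection_ratio()] defaults to this but can be overridden.
#'
#' @param optics An [optics_config()].
#' @return Radius in nm.
#' @export
diffraction_limit <- function(optics) {
  .assert(inherits(optics, "optics_config"), "expected an optics_config")
  optics$emission_wavelength_nm / (2 * optics$numerical_aperture)
}

#' Match estimated detections to ground truth in one frame
#'
#' Optimal one-to-one assignment between truth and estimated positions,
#' maximizing the number of matched pairs within `radius` and, among such
#' assignments, minimizing the total matched distance (exact subset dynamic
#' program over the truth set). Estimates farther than `radius` from every
#' truth position are flagged spurious; unmatched truths are misses.
#'
#' @param truth_positions,est_positions Matrices with 2 columns (x, y in
#'   nm); zero rows allowed.
#' @param radius Matching radius in nm.
#' @return Object of class `match_result`: `pairs` (data frame with
#'   `truth`, `est`, `dist`), `n_correct`, `n_truth`, `n_est`, `n_spurious`,
#'   `distances`.
#' @export
match_frame_detections <- function(truth_positions, est_positions, radius) {
  tp <- matrix(as.numeric(truth_positions), ncol = 2L)
  ep <- matrix(as.numeric(est_positions), ncol = 2L)
  .assert(all(is.finite(tp)) && all(is.finite(ep)), "positions must be finite")
  nt <- nrow(tp)
  ne <- nrow(ep)
  .assert(nt <= 20L, "too many truth positions for exact matching (max 20)")
  dmat <- if (nt > 0L && ne > 0L) {
    sqrt(outer(tp[, 1L], ep[, 1L], "-")^2 + outer(tp[, 2L], ep[, 2L], "-")^2)
  } else {
    matrix(0, nt, ne)
  }
  spurious <- if (ne > 0L) {
    if (nt > 0L) apply(dmat, 2L, min) > radius else rep(TRUE, ne)
  } else logical(0L)

  # DP over subsets of matched truths, estimates taken in order; each state
  # keeps the best (max matches, then min cost) and a parent pointer.
  n_states <- bitwShiftL(1L, nt)
  neg <- -1L
  matches <- rep(neg, n_states); matches[1L] <- 0L
  cost <- rep(Inf, n_states); cost[1L] <- 0
  choice <- vector("list", ne) # per estimate: chosen truth (0 = skip) per state
  all_states <- seq_len(n_states)
  for (e in seq_len(ne)) {
    # default: estimate e left unmatched (choice 0) wherever a state exists
    new_matches <- matches
    new_cost <- cost
    new_choice <- ifelse(matches >= 0L, 0L, NA_integer_)
    feas <- if (nt > 0L) which(dmat[, e] <= radius) else integer(0L)
    for (t in feas) {
      bit <- bitwShiftL(1L, t - 1L)
      # all reachable states in which truth t is still unmatched, at once
      from <- all_states[matches >= 0L &
                           bitwAnd(all_states - 1L, bit) == 0L]
      if (length(from) == 0L) next
      ns <- from + bit
      cm <- matches[from] + 1L
      cc <- cost[from] + dmat[t, e]
      upd <- cm > new_matches[ns] | (cm == new_matches[ns] & cc < new_cost[ns])
      if (any(upd)) {
        new_matches[ns[upd]] <- cm[upd]
        new_cost[ns[upd]] <- cc[upd]
        new_choice[ns[upd]] <- t
      }
    }
    matches <- new_matches
    cost <- new_cost
    choice[[e]] <- new_choice
  }
  valid <- which(matches >= 0L)
  best <- valid[order(-matches[valid], cost[valid])][1L]
  # backtrack
  pairs <- data.frame(truth = integer(0L), est = integer(0L),
                      dist = numeric(0L))
  st <- best
  for (e in rev(seq_len(ne))) {
    ch <- choice[[e]][st]
    if (!is.na(ch) && ch > 0L) {
      pairs <- rbind(data.frame(truth = ch, est = e, dist = dmat[ch, e]),
                     pairs)
      st <- st - bitwShiftL(1L, ch - 1L)
    }
  }
  structure(list(pairs = pairs, n_correct = nrow(pairs), n_truth = nt,
                 n_est = ne, n_spurious = sum(spurious),
                 distances = pairs$dist),
            class = "match_result")
}

#' Detection ratio over a whole movie
#'
#' The accuracy metric: per frame, estimated positions are matched
#' one-to-one to ground-truth positions within one matching radius
#' (typically the diffraction limit, [diffraction_limit()]); the detection
#' ratio is the total number of correct detections divided by the total
#' number of ground-truth positions. Estimates farther than the radius from
#' every truth are counted as spurious detections; the tuning convention is
#' that the ratio is only meaningful once the spurious count is zero.
#'
#' @param truth_tracks `N x Mt x 2` array of ground-truth positions (nm).
#' @param est_tracks `N x Me x 2` array of estimated positions (nm); must
#'   have the same number of frames.
#' @param radius Matching radius in nm.
#' @return List with `ratio`, `n_correct`, `n_truth`, `n_spurious`,
#'   `per_frame` (data frame) and `frames` (list of `match_result`).
#' @export
detection_ratio <- function(truth_tracks, est_tracks, radius) {
  .assert(length(dim(truth_tracks)) == 3L && length(dim(est_tracks)) == 3L,
          "tracks must be N x M x 2 arrays")
  nf <- dim(truth_tracks)[1L]
  .assert(dim(est_tracks)[1L] == nf,
          "truth and estimate disagree on frame count")
  n_truth_total <- nf * dim(truth_tracks)[2L]
  .assert(n_truth_total > 0L, "no ground-truth positions")
  frames <- vector("list", nf)
  for (n in seq_len(nf)) {
    frames[[n]] <- match_frame_detections(
      truth_tracks[n, , , drop = TRUE], est_tracks[n, , , drop = TRUE], radius)
  }
  per_frame <- data.frame(
    frame = seq_len(nf) - 1L,
    n_truth = vapply(frames, function(f) f$n_truth, integer(1L)),
    n_correct = vapply(frames, function(f) f$n_correct, integer(1L)),
    n_spurious = vapply(frames, function(f) f$n_spurious, integer(1L))
  )
  list(ratio = sum(per_frame$n_correct) / sum(per_frame$n_truth),
       n_correct = sum(per_frame$n_correct),
       n_truth = sum(per_frame$n_truth),
       n_spurious = sum(per_frame$n_spurious),
       per_frame = per_frame, frames = frames)
}
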