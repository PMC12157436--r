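#' Write candidate tracks to CSV
#'
#' Long-format table with columns `frame` (0-based), `candidate` (0-based),
#' `x_nm`, `y_nm`, `load`.
#'
#' @param positions `N x K x 2` array of positions (nm).
#' @param loads Binary vector of length `K`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(positions, loads, path) {
  .assert(is.array(positions) && length(dim(positions)) == 3L,
          "positions must be N x K x 2")
  nf <- dim(positions)[1L]
  k <- dim(positions)[2L]
  .assert(length(loads) == k, "one load per candidate")
  df <- data.frame(
    frame = rep(seq_len(nf) - 1L, times = k),
    candidate = rep(seq_len(k) - 1L, each = nf),
    x_nm = as.vector(positions[, , 1L]),
    y_nm = as.vector(positions[, , 2L]),
    load = rep(as.integer(loads), each = nf)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read candidate tracks from CSV
#'
#' Inverse of [write_tracks_csv()]; validates the schema strictly.
#'
#' @param path CSV path.
#' @return List with `positions` (`N x K x 2` array) and `loads` (length-K
#'   binary vector).
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path)
  wanted <- c("frame", "candidate", "x_nm", "y_nm", "load")
  .assert(identical(sort(names(df)), sort(wanted)),
          sprintf("track CSV must have columns %s (got %s)",
                  paste(wanted, collapse = ", "),
                  paste(names(df), collapse = ", ")))
  frames <- sort(unique(df$frame))
  cands <- sort(unique(df$candidate))
  nf <- length(frames)
  k <- length(cands)
  .assert(nrow(df) == nf * k, "track CSV must contain every (frame, candidate)")
  .assert(identical(frames, seq_len(nf) - 1L) || all(frames == seq_len(nf) - 1L),
          "frames must be 0-based and contiguous")
  positions <- array(NA_real_, dim = c(nf, k, 2L))
  loads <- integer(k)
  for (mi in seq_len(k)) {
    sub <- df[df$candidate == cands[mi], ]
    sub <- sub[order(sub$frame), ]
    positions[, mi, 1L] <- sub$x_nm
    positions[, mi, 2L] <- sub$y_nm
    lv <- unique(sub$load)
    .assert(length(lv) == 1L && lv %in% c(0L, 1L),
            "load must be constant per candidate and binary")
    loads[mi] <- lv
  }
  .assert(all(is.finite(positions)), "track CSV has non-finite positions")
  list(positions = positions, loads = loads)
}
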