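# Per-residue local score tracks: named numeric vectors keyed by the
# residue key "chain|resno|ins", values in [0,1], NA = unscored.

#' Create a local score track
#'
#' A local score track holds one score in `[0,1]` per residue, keyed by
#' the residue identity `"chain|resno|ins"`. `NA` marks residues that were
#' not scored (serialized as "X" in QMODE2 and as 0.00 in B-factors).
#'
#' @param keys character vector of residue keys (see [residue_keys()])
#' @param values numeric scores in `[0,1]`, or `NA` for unscored
#' @return named numeric vector of class `score_track`
#' @export
new_track <- function(keys, values = NA_real_) {
  values <- rep_len(as.numeric(values), length(keys))
  ok <- is.na(values) | (values >= 0 & values <= 1)
  if (!all(ok))
    stop("track values outside [0,1]: ",
         paste(format(values[!ok][seq_len(min(3, sum(!ok)))]), collapse = ", "))
  names(values) <- keys
  class(values) <- c("score_track", "numeric")
  values
}

# mean of several tracks over the union of keys, NA-aware per residue
mean_tracks <- function(tracks) {
  keys <- unique(unlist(lapply(tracks, names)))
  m <- vapply(keys, function(k) {
    v <- vapply(tracks, function(t) if (k %in% names(t)) t[[k]] else NA_real_,
                0.0)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0.0)
  new_track(keys, m)
}

track_mean <- function(track) {
  if (all(is.na(track))) NA_real_ else mean(track, na.rm = TRUE)
}
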