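# Channel conventions shared across the package.
#
# iTRAQ 8-plex reporter ions sit at nominal m/z 113-119 and 121 (120 is skipped
# because of a phenylalanine immonium interference). Channel 113 is the
# within-run reference against which all log ratios are expressed.

#' iTRAQ 8-plex channel labels
#'
#' Returns the ordered reporter-ion channel labels used throughout the
#' package: `"113" "114" "115" "116" "117" "118" "119" "121"`. Channel 113 is
#' the reference channel; every within-run log ratio is expressed against it.
#'
#' @return Character vector of the eight channel labels, in reporter m/z order.
#' @export
#' @examples
#' itraq_channels()
itraq_channels <- function() {
  c("113", "114", "115", "116", "117", "118", "119", "121")
}

#' @rdname itraq_channels
#' @export
itraq_reference_channel <- function() "113"

# Column names used for the eight count columns in wide spectrum tables.
channel_cols <- function() paste0("ch", itraq_channels())

# Deterministic, order-independent seed stream: derive a 32-bit sub-seed from
# a base seed and a string key (protein id, region label, ...). Proteins are
# fitted independently, so per-protein seeds must not depend on fit order.
derive_seed <- function(seed, key) {
  v <- utf8ToInt(as.character(key))
  h <- sum(v * seq_along(v)) %% 65521
  as.integer((as.numeric(seed) %% 100000 * 20011 + h * 7919 + 17) %% 2147483563) + 1L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_itraq <- function(msg, class) {
  rlang::abort(msg, class = c(class, "itraqdiff_error"))
}
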