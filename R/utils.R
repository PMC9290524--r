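#' Standardize a numeric vector to zero mean and unit variance
#'
#' @param x numeric vector with at least two distinct values.
#' @return numeric vector with mean 0 and sd 1.
#' @keywords internal
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-score a constant vector", call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Row-wise z-scoring of a matrix
#' @keywords internal
zscore_rows <- function(m) {
  s <- apply(m, 1L, sd)
  if (any(!is.finite(s) | s == 0)) {
    stop("zero-variance rows cannot be z-scored: ",
         paste(head(rownames(m)[!is.finite(s) | s == 0], 5L), collapse = ", "),
         call. = FALSE)
  }
  (m - rowMeans(m)) / s
}

# Module naming follows the color-code convention of coexpression network
# tools: modules are named by size rank from this fixed palette, falling back
# to numbered names when the palette is exhausted.
MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
  "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
  "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
  "darkolivegreen", "darkmagenta", "sienna"
)

#' Name modules by size rank using the standard color list
#' @param n number of module names needed.
#' @keywords internal
module_color_names <- function(n) {
  if (n <= length(MODULE_COLORS)) {
    MODULE_COLORS[seq_len(n)]
  } else {
    c(MODULE_COLORS, paste0("module_", seq.int(length(MODULE_COLORS) + 1L, n)))
  }
}

#' Reserved label for genes outside any module
#' @keywords internal
UNASSIGNED <- "unassigned"

#' Two-sided p-value for a Pearson correlation via the t distribution
#'
#' @param r correlation coefficient(s).
#' @param n number of paired observations.
#' @return two-sided p-value(s) from t with `n - 2` df.
#' @keywords internal
cor_pvalue <- function(r, n) {
  if (n < 3L) return(rep(NA_real_, length(r)))
  r <- pmin(1, pmax(-1, r))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(tt), df = n - 2)
}

#' Significance stars for p-values
#'
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, empty otherwise.
#' @keywords internal
p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' 32-bit FNV-1a hash of a character scalar (hex string)
#'
#' Used to fingerprint pipeline configurations in run manifests.
#' @keywords internal
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte; keep h a double to stay within 2^32
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply in halves to stay inside double precision
    h <- (h %% 65536 * 16777619 + (h %/% 65536 * 16777619 %% 65536) * 65536) %%
      4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Derive a substream seed from a base seed and a stage offset
#'
#' Keeps derived seeds within the 32-bit integer range.
#' @keywords internal
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% .Machine$integer.max)
}
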