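#' The sixteen binary cue configurations
#'
#' Four binary cues (A, B, X, Y) give sixteen possible stimulus patterns.
#' The enumeration order is fixed throughout the package: binary counting
#' with A as the most significant bit and Y as the least significant, so
#' row 1 is `(0,0,0,0)` (all cues absent) and row 16 is `(1,1,1,1)`.
#' All sixteen-element response and probability vectors in this package
#' follow this order.
#'
#' @return An integer matrix with 16 rows and columns `a`, `b`, `x`, `y`,
#'   each entry 0 (cue absent) or 1 (cue present). Row names are the
#'   pattern labels of [pattern_labels()].
#' @examples
#' cue_patterns()[1, ]   # all cues absent
#' cue_patterns()[16, ]  # all cues present
#' @export
cue_patterns <- function() {
  m <- as.matrix(expand.grid(y = 0:1, x = 0:1, b = 0:1, a = 0:1,
                             KEEP.OUT.ATTRS = FALSE))[, c("a", "b", "x", "y")]
  storage.mode(m) <- "integer"
  rownames(m) <- pattern_labels()
  m
}

#' Conditional-probability labels for the sixteen patterns
#'
#' Labels such as `"R|A~B~XY"` name the conditional reward probability for
#' each configuration: a bare letter means the cue is present, `~` that it
#' is absent. Order matches [cue_patterns()].
#'
#' @return Character vector of length 16.
#' @export
pattern_labels <- function() {
  m <- as.matrix(expand.grid(y = 0:1, x = 0:1, b = 0:1, a = 0:1,
                             KEEP.OUT.ATTRS = FALSE))[, c("a", "b", "x", "y")]
  apply(m, 1L, function(r) {
    paste0("R|", paste0(ifelse(r == 1, "", "~"), c("A", "B", "X", "Y"),
                        collapse = ""))
  })
}

cue_names <- function() c("a", "b", "x", "y")

# Coerce a pattern given as length-4 0/1 vector (optionally named) to the
# canonical named integer vector; errors on anything else.
as_cue_pattern <- function(pattern) {
  if (is.list(pattern)) pattern <- unlist(pattern)
  if (length(pattern) != 4L || !all(pattern %in% c(0, 1))) {
    stop("a cue pattern is a length-4 vector of 0/1 indicators (a, b, x, y)",
         call. = FALSE)
  }
  p <- as.integer(pattern)
  names(p) <- cue_names()
  p
}
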