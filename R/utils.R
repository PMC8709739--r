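`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards so library functions never clobber a user session.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_expression_matrix <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric features x samples matrix", arg),
         call. = FALSE)
  }
  if (is.null(rownames(x))) {
    stop(sprintf("`%s` must have feature identifiers as rownames", arg),
         call. = FALSE)
  }
  invisible(x)
}

row_sds <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1))
}

# Strip the layer prefix ("G-"/"M-") from a module label.
strip_layer_prefix <- function(labels) sub("^[GM]-", "", labels)

is_grey_label <- function(labels) strip_layer_prefix(labels) == "grey"

#' Fixed module color palette
#'
#' Module labels are assigned from this frozen palette in order of
#' decreasing module size, so module names are reproducible across runs.
#' `"grey"` is reserved for unassigned features and never appears here.
#'
#' @return Character vector of color names.
#' @export
module_color_palette <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
    "pink", "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta")
}
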