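#' Tercile scheme: named cut-offs mapping a continuous score to three groups
#'
#' A tercile scheme carries two ordered cut points, the direction of the score
#' (whether high or low values are the unfavourable end) and a boundary rule
#' saying which group owns a value that falls exactly on a cut.
#'
#' Two boundary rules are used by the shipped schemes:
#' * `"closed_lower"`: `x <= b1` is band 1, `b1 < x <= b2` band 2 (the
#'   lifestyle-score convention, where the printed cut-offs read "<= 21",
#'   "22-32", "> 32");
#' * `"closed_middle"`: both cut values belong to the middle band, i.e.
#'   `b1 <= x <= b2` is band 2 (the PNI/NRI convention, where the printed
#'   middle band is closed on both endpoints).
#'
#' Bands are counted along the value axis; with `direction =
#' "higher_is_worse"` band i is labelled `Ti`, with `"lower_is_worse"` the
#' labelling is reversed so that `T3` is always the unfavourable group.
#'
#' @param name scheme name (used in reports).
#' @param boundaries numeric vector of two strictly increasing cut points.
#' @param direction `"higher_is_worse"` or `"lower_is_worse"`.
#' @param boundary_rule `"closed_lower"` or `"closed_middle"`.
#' @param labels three group labels, low to high risk.
#' @return An object of class `tercile_scheme`.
#' @examples
#' cut_terciles(c(21, 22, 33), ls_scheme())
#' cut_terciles(c(57, 55, 50), pni_scheme())
#' @export
tercile_scheme <- function(name, boundaries,
                           direction = c("higher_is_worse", "lower_is_worse"),
                           boundary_rule = c("closed_lower", "closed_middle"),
                           labels = c("T1", "T2", "T3")) {
  direction <- match.arg(direction)
  boundary_rule <- match.arg(boundary_rule)
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) != 2 || any(!is.finite(boundaries))) {
    abort("`boundaries` must be two finite numbers")
  }
  if (length(labels) != 3) abort("`labels` must have length 3")
  degenerate <- boundaries[1] >= boundaries[2]
  if (degenerate && boundaries[1] > boundaries[2]) {
    abort("`boundaries` must be ordered (b1 < b2)")
  }
  structure(
    list(
      name = name, boundaries = boundaries, direction = direction,
      boundary_rule = boundary_rule, labels = labels, degenerate = degenerate
    ),
    class = "tercile_scheme"
  )
}

#' @export
print.tercile_scheme <- function(x, ...) {
  cat("<tercile_scheme> ", x$name, "\n",
    "  cuts: ", x$boundaries[1], " / ", x$boundaries[2],
    "  (", x$boundary_rule, ", ", x$direction, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Assign tercile labels to score values
#'
#' Maps every finite value to exactly one of the scheme's three labels;
#' missing values stay `NA`.
#'
#' @param x numeric score values.
#' @param scheme a [tercile_scheme()].
#' @return A factor with the scheme's labels (risk-ordered `T1 < T2 < T3`).
#' @export
cut_terciles <- function(x, scheme) {
  stopifnot(inherits(scheme, "tercile_scheme"))
  b <- scheme$boundaries
  band <- if (scheme$boundary_rule == "closed_lower") {
    1L + (x > b[1]) + (x > b[2])
  } else {
    1L + (x >= b[1]) + (x > b[2])
  }
  idx <- if (scheme$direction == "higher_is_worse") band else 4L - band
  factor(scheme$labels[idx], levels = scheme$labels, ordered = FALSE)
}

#' Fixed tercile schemes for the shipped scores
#'
#' `ls_scheme()` uses the published lifestyle-score cut-offs (<= 21 healthy /
#' 22-32 moderate / > 32 unhealthy). `pni_scheme()` and `nri_scheme()` encode
#' the published nutritional-index bands, where *lower* values are the
#' higher-risk end and exact boundary values belong to the moderate band
#' (PNI: > 56.35 / 53.25-56.35 / < 53.25; NRI: > 122.8 / 115.2-122.8 /
#' < 115.2).
#'
#' @return A [tercile_scheme()].
#' @export
ls_scheme <- function() {
  tercile_scheme("LS", c(21, 32), "higher_is_worse", "closed_lower")
}

#' @rdname ls_scheme
#' @export
pni_scheme <- function() {
  tercile_scheme("PNI", c(53.25, 56.35), "lower_is_worse", "closed_middle")
}

#' @rdname ls_scheme
#' @export
nri_scheme <- function() {
  tercile_scheme("NRI", c(115.2, 122.8), "lower_is_worse", "closed_middle")
}

#' Empirical tercile scheme from observed values
#'
#' Cut points are the empirical 1/3 and 2/3 quantiles computed with the
#' inverse-ECDF definition (`type = 1`), combined with the `closed_lower`
#' boundary rule so that tied boundary values fall into the lower group -
#' the same convention as the fixed "<= 21" lifestyle-score cut.
#'
#' @param values numeric vector with at least 3 non-missing values.
#' @param name scheme name.
#' @param direction passed to [tercile_scheme()].
#' @return A [tercile_scheme()]; degenerate schemes (identical cut points,
#'   e.g. constant input) are flagged with a warning and map everything to
#'   one group.
#' @export
empirical_terciles <- function(values, name = "empirical",
                               direction = "higher_is_worse") {
  values <- values[!is.na(values)]
  if (length(values) < 3) abort("need at least 3 non-missing values")
  cuts <- unname(quantile(values, c(1 / 3, 2 / 3), type = 1))
  if (cuts[1] >= cuts[2]) {
    warn(paste0("degenerate tercile scheme for '", name,
                "': identical cut points ", cuts[1]))
    # widen infinitesimally so the object stays well-formed; all values at or
    # below the cut land in one group
    cuts[2] <- cuts[1] + .Machine$double.eps * max(1, abs(cuts[1]))
  }
  tercile_scheme(name, cuts, direction, "closed_lower")
}
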