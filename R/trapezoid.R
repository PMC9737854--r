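#' Trapezoidal fuzzy set
#'
#' Constructs a trapezoidal fuzzy set \code{(l, k1, k2, r)}: membership is 0
#' outside the support \code{[l, r]}, 1 on the kernel \code{[k1, k2]}, and
#' linear on the two shoulders. Degenerate shoulders (\code{l == k1} and/or
#' \code{k2 == r}) are allowed; membership at the shared point is 1 (the
#' kernel wins), so a set like \code{(0, 0, 0, 14)} attains full membership
#' at 0 exactly.
#'
#' @param l Left support bound.
#' @param k1 Kernel start.
#' @param k2 Kernel end.
#' @param r Right support bound.
#' @param label Optional text tag (the linguistic value name).
#' @return An object of class \code{fuzzy_trapezoid}.
#' @examples
#' s <- fuzzy_trapezoid(0, 14, 26, 40, label = "medium")
#' trapezoid_membership(s, c(7, 20, 33))
#' @export
fuzzy_trapezoid <- function(l, k1, k2, r, label = NULL) {
  stopifnot(is.numeric(l), is.numeric(k1), is.numeric(k2), is.numeric(r),
            length(l) == 1L, length(k1) == 1L, length(k2) == 1L, length(r) == 1L)
  if (!(l <= k1 && k1 <= k2 && k2 <= r)) {
    stop("trapezoid parameters must satisfy l <= k1 <= k2 <= r, got (",
         l, ", ", k1, ", ", k2, ", ", r, ")", call. = FALSE)
  }
  structure(list(l = l, k1 = k1, k2 = k2, r = r,
                 label = if (is.null(label)) NA_character_ else as.character(label)),
            class = "fuzzy_trapezoid")
}

#' @export
print.fuzzy_trapezoid <- function(x, ...) {
  cat(sprintf("<fuzzy_trapezoid%s (%g, %g, %g, %g)>\n",
              if (is.na(x$label)) "" else paste0(" '", x$label, "'"),
              x$l, x$k1, x$k2, x$r))
  invisible(x)
}

#' Membership degree of a trapezoidal set
#'
#' Total function over the reals: 0 outside the support, 1 on the kernel,
#' linear on the shoulders. Vectorised over \code{x}.
#'
#' @param set A \code{fuzzy_trapezoid}.
#' @param x Numeric vector of evaluation points.
#' @return Numeric vector of degrees in \code{[0, 1]}.
#' @export
trapezoid_membership <- function(set, x) {
  stopifnot(inherits(set, "fuzzy_trapezoid"), is.numeric(x))
  mu <- numeric(length(x))
  mu[x >= set$k1 & x <= set$k2] <- 1
  if (set$k1 > set$l) {
    i <- x > set$l & x < set$k1
    mu[i] <- (x[i] - set$l) / (set$k1 - set$l)
  }
  if (set$r > set$k2) {
    i <- x > set$k2 & x < set$r
    mu[i] <- (set$r - x[i]) / (set$r - set$k2)
  }
  mu
}

#' Linguistic variable
#'
#' A named domain interval carrying an ordered list of labelled trapezoidal
#' sets (e.g. low / medium / high). Every set's support must lie within the
#' domain; a small tolerance accommodates published set parameters that
#' overshoot the nominal instrument range by a point.
#'
#' @param name Variable name.
#' @param domain Length-2 numeric, the closed domain interval.
#' @param sets List of \code{fuzzy_trapezoid}s, each with a unique label.
#' @param overshoot Allowed excess of a support bound beyond the domain
#'   (default 1; the personal-accomplishment partition is printed with
#'   support bound 49 on a 0--48 instrument).
#' @return An object of class \code{fuzzy_variable}.
#' @export
fuzzy_variable <- function(name, domain, sets, overshoot = 1) {
  stopifnot(is.character(name), length(domain) == 2L, domain[1] < domain[2],
            is.list(sets), length(sets) >= 1L)
  labs <- vapply(sets, function(s) s$label, character(1))
  if (anyNA(labs) || anyDuplicated(labs)) {
    stop("every set of a fuzzy_variable needs a unique label", call. = FALSE)
  }
  for (s in sets) {
    if (s$l < domain[1] - overshoot || s$r > domain[2] + overshoot) {
      stop("support of set '", s$label, "' [", s$l, ", ", s$r,
           "] lies outside domain [", domain[1], ", ", domain[2], "]",
           call. = FALSE)
    }
  }
  structure(list(name = name, domain = as.numeric(domain),
                 sets = sets, labels = labs),
            class = "fuzzy_variable")
}

#' @export
print.fuzzy_variable <- function(x, ...) {
  cat(sprintf("<fuzzy_variable '%s' on [%g, %g]: %s>\n", x$name,
              x$domain[1], x$domain[2], paste(x$labels, collapse = "/")))
  invisible(x)
}

#' Fuzzify a crisp value
#'
#' Evaluates the membership of \code{x} in every labelled set of the
#' variable. For the partitions used by the PLUS model the degrees sum to 1
#' at every domain point (Ruspini partition).
#'
#' @param var A \code{fuzzy_variable}.
#' @param x A single numeric value inside the variable's domain.
#' @return Named numeric vector, one degree per label.
#' @export
fuzzify <- function(var, x) {
  stopifnot(inherits(var, "fuzzy_variable"), is.numeric(x), length(x) == 1L)
  if (is.na(x) || x < var$domain[1] || x > var$domain[2]) {
    stop("value ", x, " outside domain [", var$domain[1], ", ",
         var$domain[2], "] of variable '", var$name, "'", call. = FALSE)
  }
  deg <- vapply(var$sets, trapezoid_membership, numeric(1), x = x)
  names(deg) <- var$labels
  deg
}
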