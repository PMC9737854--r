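#' Fuzzy inference rule
#'
#' An IF--THEN rule whose antecedent is a conjunction of
#' (variable, linguistic value) clauses and whose consequent names a set of
#' the output variable. Premises are aggregated by product.
#'
#' @param antecedent Named character vector: names are input-variable names,
#'   values are set labels.
#' @param consequent Label of an output set.
#' @return An object of class \code{fuzzy_rule}.
#' @export
fuzzy_rule <- function(antecedent, consequent) {
  stopifnot(is.character(antecedent), length(antecedent) >= 1L,
            !is.null(names(antecedent)), all(nzchar(names(antecedent))),
            is.character(consequent), length(consequent) == 1L)
  structure(list(antecedent = antecedent, consequent = consequent),
            class = "fuzzy_rule")
}

#' Operator configuration of a Mamdani system
#'
#' Fixed to the configuration used throughout the PLUS model: product
#' aggregation of premises, minimum (clip) implication, maximum accumulation
#' and centre-of-gravity defuzzification. Alternatives are rejected so a
#' mis-specified config file cannot silently change the semantics.
#'
#' @param premise,implication,accumulation,defuzzification Operator names.
#' @return An object of class \code{operator_config}.
#' @export
operator_config <- function(premise = "prod", implication = "min",
                            accumulation = "max", defuzzification = "cog") {
  premise <- match.arg(premise, "prod")
  implication <- match.arg(implication, "min")
  accumulation <- match.arg(accumulation, "max")
  defuzzification <- match.arg(defuzzification, "cog")
  structure(list(premise = premise, implication = implication,
                 accumulation = accumulation, defuzzification = defuzzification),
            class = "operator_config")
}

#' Mamdani fuzzy inference system
#'
#' Bundles input variables, one output variable, a rule base and the operator
#' configuration. The defuzzification domain may extend beyond the output
#' variable's nominal domain so that extended boundary sets integrate fully
#' (this is how the model reaches exactly 0 and exactly 1 at the scale ends).
#'
#' @param inputs List of \code{fuzzy_variable}s.
#' @param output A \code{fuzzy_variable}.
#' @param rules List of \code{fuzzy_rule}s.
#' @param operators An \code{operator_config}.
#' @param defuzz_domain Length-2 numeric; defaults to the output domain.
#' @return An object of class \code{mamdani_system}.
#' @export
mamdani_system <- function(inputs, output, rules,
                           operators = operator_config(),
                           defuzz_domain = output$domain) {
  stopifnot(is.list(inputs), length(inputs) >= 1L,
            inherits(output, "fuzzy_variable"),
            is.list(rules), length(rules) >= 1L,
            inherits(operators, "operator_config"),
            length(defuzz_domain) == 2L, defuzz_domain[1] < defuzz_domain[2])
  in_names <- vapply(inputs, function(v) v$name, character(1))
  if (anyDuplicated(in_names)) stop("duplicate input variable names", call. = FALSE)
  names(inputs) <- in_names
  for (rl in rules) {
    for (vn in names(rl$antecedent)) {
      if (!vn %in% in_names) {
        stop("rule references unknown variable '", vn, "'", call. = FALSE)
      }
      if (!rl$antecedent[[vn]] %in% inputs[[vn]]$labels) {
        stop("rule references unknown label '", rl$antecedent[[vn]],
             "' of variable '", vn, "'", call. = FALSE)
      }
    }
    if (!rl$consequent %in% output$labels) {
      stop("rule consequent '", rl$consequent, "' not an output label",
           call. = FALSE)
    }
  }
  structure(list(inputs = inputs, output = output, rules = rules,
                 operators = operators,
                 defuzz_domain = as.numeric(defuzz_domain)),
            class = "mamdani_system")
}

#' @export
print.mamdani_system <- function(x, ...) {
  cat(sprintf("<mamdani_system: %d input(s), %d rule(s), output '%s' on [%g, %g]>\n",
              length(x$inputs), length(x$rules), x$output$name,
              x$defuzz_domain[1], x$defuzz_domain[2]))
  invisible(x)
}

#' Fire the rule base
#'
#' Computes each rule's activation as the product of the membership degrees
#' of its antecedent clauses.
#'
#' @param system A \code{mamdani_system}.
#' @param inputs Named numeric vector or list of crisp input values, one per
#'   antecedent variable.
#' @return Numeric vector of activations in \code{[0, 1]}, one per rule.
#' @export
fire_rules <- function(system, inputs) {
  stopifnot(inherits(system, "mamdani_system"))
  inputs <- unlist(inputs)
  degs <- lapply(system$inputs, function(v) {
    if (!v$name %in% names(inputs)) {
      stop("missing input for variable '", v$name, "'", call. = FALSE)
    }
    fuzzify(v, inputs[[v$name]])
  })
  vapply(system$rules, function(rl) {
    prod(vapply(seq_along(rl$antecedent), function(i) {
      degs[[names(rl$antecedent)[i]]][[rl$antecedent[[i]]]]
    }, numeric(1)))
  }, numeric(1))
}

# Breakpoints of min(h, membership of set) over [lo, hi]; the clipped
# trapezoid is continuous piecewise-linear so its exact breakpoints are the
# set corners plus the two points where the shoulders cross the clip level.
.clip_breakpoints <- function(set, h, lo, hi) {
  xs <- c(set$l, set$k1, set$k2, set$r)
  if (h < 1) {
    if (set$k1 > set$l) xs <- c(xs, set$l + (set$k1 - set$l) * h)
    if (set$r > set$k2) xs <- c(xs, set$r - (set$r - set$k2) * h)
  }
  sort(unique(pmin(pmax(xs, lo), hi)))
}

.clip_eval <- function(set, h, x) pmin(h, trapezoid_membership(set, x))

#' Clip and accumulate fired consequents
#'
#' Applies minimum implication (clipping each consequent set at its rule's
#' activation) and maximum accumulation (the pointwise upper envelope), and
#' returns the result as an exact piecewise-linear curve on the
#' defuzzification domain. Breakpoints include every clipped-set corner and
#' every crossing between clipped sets, so linear interpolation between the
#' returned points is exact.
#'
#' @param system A \code{mamdani_system}.
#' @param activations Numeric vector of rule activations (from
#'   \code{\link{fire_rules}}).
#' @return A list with components \code{x} and \code{mu} (class
#'   \code{fuzzy_pwl}): strictly increasing breakpoints and their membership
#'   values.
#' @export
clip_and_accumulate <- function(system, activations) {
  stopifnot(inherits(system, "mamdani_system"),
            length(activations) == length(system$rules),
            all(activations >= 0), all(activations <= 1))
  lo <- system$defuzz_domain[1]; hi <- system$defuzz_domain[2]
  # group by consequent: max accumulation makes only the per-label max clip matter
  h_by_label <- tapply(activations,
                       vapply(system$rules, `[[`, character(1), "consequent"),
                       max)
  h_by_label <- h_by_label[h_by_label > 0]
  if (length(h_by_label) == 0L) {
    stop("degenerate inference: no rule fired with positive activation",
         call. = FALSE)
  }
  out_sets <- system$output$sets
  names(out_sets) <- system$output$labels
  pieces <- lapply(names(h_by_label), function(lb) {
    list(set = out_sets[[lb]], h = unname(h_by_label[[lb]]))
  })

  xs <- sort(unique(c(lo, hi, unlist(lapply(pieces, function(p)
    .clip_breakpoints(p$set, p$h, lo, hi))))))
  # refine with pairwise crossings: between consecutive candidates every piece
  # is linear, so two pieces cross at most once per cell
  if (length(pieces) > 1L) {
    extra <- numeric(0)
    vals <- vapply(pieces, function(p) .clip_eval(p$set, p$h, xs),
                   numeric(length(xs)))
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(xs))
    for (i in seq_len(length(xs) - 1L)) {
      a <- xs[i]; b <- xs[i + 1L]
      for (p1 in seq_len(length(pieces) - 1L)) {
        for (p2 in (p1 + 1L):length(pieces)) {
          d0 <- vals[i, p1] - vals[i, p2]
          d1 <- vals[i + 1L, p1] - vals[i + 1L, p2]
          if (d0 * d1 < 0) {
            extra <- c(extra, a + (b - a) * d0 / (d0 - d1))
          }
        }
      }
    }
    xs <- sort(unique(c(xs, extra)))
  }
  mu <- rep(0, length(xs))
  for (p in pieces) mu <- pmax(mu, .clip_eval(p$set, p$h, xs))
  structure(list(x = xs, mu = mu), class = "fuzzy_pwl")
}

#' Centre-of-gravity defuzzification
#'
#' Exact centroid of a piecewise-linear membership curve: area and first
#' moment are accumulated per linear segment in closed form, so boundary
#' cases (extended triangles centred at 0 or 1) defuzzify to exactly 0 or 1.
#'
#' @param curve A \code{fuzzy_pwl} (see \code{\link{clip_and_accumulate}}),
#'   or any list with strictly increasing \code{x} and matching \code{mu}.
#' @return The crisp centroid value.
#' @export
defuzzify_cog <- function(curve) {
  x <- curve$x; mu <- curve$mu
  stopifnot(is.numeric(x), is.numeric(mu), length(x) == length(mu),
            length(x) >= 2L, all(diff(x) > 0), all(mu >= 0))
  dx <- diff(x)
  y1 <- mu[-length(mu)]; y2 <- mu[-1L]
  x1 <- x[-length(x)]; x2 <- x[-1L]
  area <- sum(dx * (y1 + y2) / 2)
  if (area <= 0) {
    stop("degenerate inference: accumulated curve has zero area", call. = FALSE)
  }
  moment <- sum(dx * (x1 * (2 * y1 + y2) + x2 * (y1 + 2 * y2)) / 6)
  moment / area
}

#' Run a full Mamdani inference
#'
#' Fuzzify, fire the rules (product premise), clip (min implication),
#' accumulate (max) and defuzzify (centre of gravity).
#'
#' @param system A \code{mamdani_system}.
#' @param inputs Named numeric vector/list of crisp inputs.
#' @param trace If \code{TRUE}, attach the label degrees, rule activations
#'   and accumulated curve to the result.
#' @return The crisp output, or (with \code{trace = TRUE}) a list with
#'   \code{value}, \code{memberships}, \code{activations} and \code{curve}.
#' @export
infer <- function(system, inputs, trace = FALSE) {
  act <- fire_rules(system, inputs)
  curve <- clip_and_accumulate(system, act)
  value <- defuzzify_cog(curve)
  if (!trace) return(value)
  inputs <- unlist(inputs)
  memb <- lapply(system$inputs, function(v) fuzzify(v, inputs[[v$name]]))
  names(act) <- vapply(seq_along(system$rules), function(i) {
    rl <- system$rules[[i]]
    paste0("R", i, ": ",
           paste(paste0(names(rl$antecedent), "=", rl$antecedent),
                 collapse = " & "), " -> ", rl$consequent)
  }, character(1))
  list(value = value, memberships = memb, activations = act, curve = curve)
}
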