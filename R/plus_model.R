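#' @importFrom stats sd quantile pt setNames
NULL

# The six clinimetric scales feeding the PLUS hierarchy. Partitions are the
# published low/medium/high trapezoids; higher_better marks the two scales
# whose raw direction is already "higher is better" (SWLS, MBI personal
# accomplishment). Note the personal-accomplishment partition is printed
# with support bound 49 on a 0-48 instrument; the published parameters are
# kept verbatim, so a perfect PA score normalizes slightly below 1.
.plus_scale_table <- function() {
  list(
    pss10 = list(domain = c(0, 40), higher_better = FALSE,
                 low = c(0, 0, 0, 14), medium = c(0, 14, 26, 40),
                 high = c(26, 40, 40, 40)),
    swls = list(domain = c(5, 35), higher_better = TRUE,
                low = c(5, 5, 5, 15), medium = c(5, 15, 24, 35),
                high = c(24, 35, 35, 35)),
    nmq = list(domain = c(0, 40), higher_better = FALSE,
               low = c(0, 0, 0, 14), medium = c(0, 14, 26, 40),
               high = c(26, 40, 40, 40)),
    mbi_ee = list(domain = c(0, 54), higher_better = FALSE,
                  low = c(0, 0, 0, 16), medium = c(0, 16, 27, 54),
                  high = c(27, 54, 54, 54)),
    mbi_dp = list(domain = c(0, 30), higher_better = FALSE,
                  low = c(0, 0, 0, 8), medium = c(0, 8, 14, 30),
                  high = c(14, 30, 30, 30)),
    mbi_pa = list(domain = c(0, 48), higher_better = TRUE,
                  low = c(0, 0, 0, 31), medium = c(0, 31, 39, 49),
                  high = c(39, 49, 49, 49))
  )
}

#' Names and legal ranges of the PLUS input scales
#'
#' @return A data frame with one row per scale: id, lower and upper bound of
#'   the legal raw-score interval, and whether a higher raw score is better.
#' @export
plus_scales <- function() {
  tab <- .plus_scale_table()
  data.frame(
    scale = names(tab),
    min = vapply(tab, function(s) s$domain[1], numeric(1)),
    max = vapply(tab, function(s) s$domain[2], numeric(1)),
    higher_better = vapply(tab, function(s) s$higher_better, logical(1)),
    row.names = NULL
  )
}

.scale_variable <- function(id) {
  s <- .plus_scale_table()[[id]]
  mk <- function(p, lb) fuzzy_trapezoid(p[1], p[2], p[3], p[4], label = lb)
  fuzzy_variable(id, s$domain, list(
    mk(s$low, "low"), mk(s$medium, "medium"), mk(s$high, "high")
  ))
}

#' Three-level normalized output variable
#'
#' The tier-1 output partition on \code{[0, 1]}: a low triangle at 0, a mid
#' triangle at 0.5 and a high triangle at 1. With \code{extended = TRUE} the
#' boundary triangles are widened symmetrically beyond the unit interval
#' (low to \code{(-0.5, 0, 0, 0.5)}, high to \code{(0.5, 1, 1, 1.5)}) so
#' that centre-of-gravity defuzzification can reach exactly 0 and exactly 1.
#'
#' @param extended Use the widened boundary sets (the model default).
#' @param name Variable name.
#' @return A \code{fuzzy_variable}.
#' @export
tier1_output_variable <- function(extended = TRUE, name = "e") {
  lo <- if (extended) c(-0.5, 0, 0, 0.5) else c(0, 0, 0, 0.5)
  hi <- if (extended) c(0.5, 1, 1, 1.5) else c(0.5, 1, 1, 1)
  fuzzy_variable(name, c(0, 1), list(
    fuzzy_trapezoid(lo[1], lo[2], lo[3], lo[4], label = "low"),
    fuzzy_trapezoid(0, 0.5, 0.5, 1, label = "mid"),
    fuzzy_trapezoid(hi[1], hi[2], hi[3], hi[4], label = "high")
  ), overshoot = 0.5)
}

#' Four-level module output variable
#'
#' The aggregation-tier output partition on \code{[0, 1]}: four triangles
#' centred at 0, 1/3, 2/3 and 1 (exact thirds; the published 0.333/0.667 are
#' decimal roundings). With \code{extended = TRUE} the boundary triangles
#' widen to \code{(-1/3, 0, 0, 1/3)} and \code{(2/3, 1, 1, 4/3)}.
#'
#' @inheritParams tier1_output_variable
#' @return A \code{fuzzy_variable}.
#' @export
module_output_variable <- function(extended = TRUE, name = "o") {
  lo <- if (extended) c(-1 / 3, 0, 0, 1 / 3) else c(0, 0, 0, 1 / 3)
  hi <- if (extended) c(2 / 3, 1, 1, 4 / 3) else c(2 / 3, 1, 1, 1)
  fuzzy_variable(name, c(0, 1), list(
    fuzzy_trapezoid(lo[1], lo[2], lo[3], lo[4], label = "o1"),
    fuzzy_trapezoid(0, 1 / 3, 1 / 3, 2 / 3, label = "o2"),
    fuzzy_trapezoid(1 / 3, 2 / 3, 2 / 3, 1, label = "o3"),
    fuzzy_trapezoid(hi[1], hi[2], hi[3], hi[4], label = "o4")
  ), overshoot = 1 / 3)
}

#' Two-level module input variable
#'
#' Aggregation-tier inputs are normalized values on \code{[0, 1]} split into
#' two complementary ramps: low \code{(0, 0, 0, 1)} and high
#' \code{(0, 1, 1, 1)}.
#'
#' @param name Variable name.
#' @return A \code{fuzzy_variable}.
#' @export
module_input_variable <- function(name) {
  fuzzy_variable(name, c(0, 1), list(
    fuzzy_trapezoid(0, 0, 0, 1, label = "L"),
    fuzzy_trapezoid(0, 1, 1, 1, label = "H")
  ))
}

# Tier-1 normalizer: single-input Mamdani system mapping a raw scale score
# to [0, 1], "the higher, the better". Scales whose raw direction is
# "higher is worse" get the reversed consequent assignment.
.build_normalizer <- function(id) {
  s <- .plus_scale_table()[[id]]
  cons <- if (s$higher_better) c(low = "low", medium = "mid", high = "high")
          else c(low = "high", medium = "mid", high = "low")
  mamdani_system(
    inputs = list(.scale_variable(id)),
    output = tier1_output_variable(extended = TRUE),
    rules = lapply(names(cons), function(lb)
      fuzzy_rule(setNames(lb, id), cons[[lb]])),
    defuzz_domain = c(-0.5, 1.5)
  )
}

# Two-input aggregation module (mental state: stress + life satisfaction).
# The published description splits module inputs into two-valued variables;
# the rule base itself is not printed, so the minimal analogue of the
# printed three-input base is used: LL -> low, LH/HL -> mid, HH -> high on
# the three-level output partition. This reconstruction preserves the
# mirror symmetry of the printed base.
.build_module2 <- function(in_names = c("a", "b")) {
  combos <- expand.grid(x = c("L", "H"), y = c("L", "H"),
                        stringsAsFactors = FALSE)
  cons <- c(LL = "low", HL = "mid", LH = "mid", HH = "high")[
    paste0(combos$x, combos$y)]
  mamdani_system(
    inputs = lapply(in_names, module_input_variable),
    output = tier1_output_variable(extended = TRUE),
    rules = lapply(seq_len(nrow(combos)), function(i)
      fuzzy_rule(setNames(c(combos$x[i], combos$y[i]), in_names),
                 unname(cons[i]))),
    defuzz_domain = c(-0.5, 1.5)
  )
}

# Three-input aggregation module (burnout; also the final tier). The eight
# published rules: output level = number of inputs at H, via the four-level
# partition o1..o4.
.build_module3 <- function(in_names = c("a", "b", "c")) {
  combos <- expand.grid(x = c("L", "H"), y = c("L", "H"), z = c("L", "H"),
                        stringsAsFactors = FALSE)
  n_high <- (combos$x == "H") + (combos$y == "H") + (combos$z == "H")
  mamdani_system(
    inputs = lapply(in_names, module_input_variable),
    output = module_output_variable(extended = TRUE),
    rules = lapply(seq_len(nrow(combos)), function(i)
      fuzzy_rule(setNames(c(combos$x[i], combos$y[i], combos$z[i]), in_names),
                 paste0("o", n_high[i] + 1L))),
    defuzz_domain = c(-1 / 3, 4 / 3)
  )
}

#' Build the default PLUS model
#'
#' Constructs the full three-tier hierarchy: six tier-1 normalizers (one per
#' scale), the two-input mental-state module (PSS10 + SWLS), the three-input
#' burnout module (MBI emotional exhaustion, depersonalization, personal
#' accomplishment) and the final three-input aggregator (mental, physical,
#' burnout). The physical module has a single input (NMQ) and passes its
#' normalized value through unchanged.
#'
#' @return An object of class \code{plus_model}.
#' @examples
#' m <- plus_default_model()
#' plus_evaluate(c(pss10 = 20, swls = 19.5, nmq = 20,
#'                 mbi_ee = 21.5, mbi_dp = 11, mbi_pa = 35), model = m)
#' @export
plus_default_model <- function() {
  ids <- names(.plus_scale_table())
  structure(list(
    normalizers = setNames(lapply(ids, .build_normalizer), ids),
    module_mental = .build_module2(c("pss10", "swls")),
    module_burnout = .build_module3(c("mbi_ee", "mbi_dp", "mbi_pa")),
    final = .build_module3(c("mental", "physical", "burnout"))
  ), class = "plus_model")
}

#' @export
print.plus_model <- function(x, ...) {
  cat("<plus_model: 6 tier-1 normalizers; mental (2-in), physical (passthrough),",
      "burnout (3-in); final 3-in aggregator>\n")
  invisible(x)
}

#' Tier-1 fuzzy normalization of one raw scale score
#'
#' Maps a raw questionnaire score to a normalized value in \code{[0, 1]}
#' with the meaning "the higher, the better", via single-input Mamdani
#' inference with the extended boundary output sets (so the best and worst
#' raw scores map to exactly 1 and exactly 0 for most scales).
#'
#' @param scale One of \code{"pss10"}, \code{"swls"}, \code{"nmq"},
#'   \code{"mbi_ee"}, \code{"mbi_dp"}, \code{"mbi_pa"}.
#' @param x Raw score within the scale's legal range.
#' @param model A \code{plus_model}.
#' @return Normalized value in \code{[0, 1]}.
#' @examples
#' plus_normalize("pss10", 0)   # best possible -> 1
#' plus_normalize("pss10", 40)  # worst possible -> 0
#' @export
plus_normalize <- function(scale, x, model = plus_default_model()) {
  stopifnot(inherits(model, "plus_model"))
  scale <- match.arg(scale, names(model$normalizers))
  sys <- model$normalizers[[scale]]
  dom <- sys$inputs[[1]]$domain
  if (is.na(x) || x < dom[1] || x > dom[2]) {
    stop("raw ", scale, " score must lie in [", dom[1], ", ", dom[2],
         "], got ", x, call. = FALSE)
  }
  infer(sys, setNames(x, scale))
}

#' Evaluate a two-input aggregation module
#'
#' @param a,b Normalized inputs in \code{[0, 1]}.
#' @param system A two-input module system; defaults to the mental-state
#'   module of the default model.
#' @return Module output in \code{[0, 1]}.
#' @export
plus_module2 <- function(a, b, system = plus_default_model()$module_mental) {
  stopifnot(a >= 0, a <= 1, b >= 0, b <= 1)
  infer(system, setNames(c(a, b), names(system$inputs)))
}

#' Evaluate a three-input aggregation module
#'
#' @param a,b,c Normalized inputs in \code{[0, 1]}.
#' @param system A three-input module system; defaults to the burnout module
#'   of the default model.
#' @return Module output in \code{[0, 1]}.
#' @export
plus_module3 <- function(a, b, c, system = plus_default_model()$module_burnout) {
  stopifnot(a >= 0, a <= 1, b >= 0, b <= 1, c >= 0, c <= 1)
  infer(system, setNames(c(a, b, c), names(system$inputs)))
}

#' Evaluate the full PLUS hierarchy for one assessment
#'
#' Normalizes the six raw scores (tier 1), aggregates them into the mental,
#' physical and burnout context modules (tier 2; the physical module passes
#' the normalized NMQ value through unchanged), and combines the three module
#' outputs into the final PLUS life-satisfaction score (tier 3).
#'
#' @param scores Named numeric vector or list with elements \code{pss10}
#'   (0--40), \code{swls} (5--35), \code{nmq} (0--40), \code{mbi_ee} (0--54),
#'   \code{mbi_dp} (0--30), \code{mbi_pa} (0--48).
#' @param model A \code{plus_model}.
#' @param trace Keep the per-tier rule activations and curves.
#' @return An object of class \code{plus_result}: list with \code{normalized}
#'   (six tier-1 values), \code{module_mental}, \code{module_physical},
#'   \code{module_burnout}, \code{plus_score}, and optionally \code{trace}.
#' @export
plus_evaluate <- function(scores, model = plus_default_model(), trace = FALSE) {
  stopifnot(inherits(model, "plus_model"))
  scores <- unlist(scores)
  ids <- names(model$normalizers)
  missing <- setdiff(ids, names(scores))
  if (length(missing) > 0L) {
    stop("missing score(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  tier1 <- lapply(ids, function(id) {
    sys <- model$normalizers[[id]]
    dom <- sys$inputs[[1]]$domain
    x <- scores[[id]]
    if (is.na(x) || x < dom[1] || x > dom[2]) {
      stop("raw ", id, " score must lie in [", dom[1], ", ", dom[2],
           "], got ", x, call. = FALSE)
    }
    infer(sys, setNames(x, id), trace = trace)
  })
  names(tier1) <- ids
  val <- function(r) if (trace) r$value else r
  normalized <- vapply(tier1, val, numeric(1))

  mental <- infer(model$module_mental,
                  c(pss10 = normalized[["pss10"]], swls = normalized[["swls"]]),
                  trace = trace)
  physical <- normalized[["nmq"]]  # single-source module: direct passthrough
  burnout <- infer(model$module_burnout,
                   c(mbi_ee = normalized[["mbi_ee"]],
                     mbi_dp = normalized[["mbi_dp"]],
                     mbi_pa = normalized[["mbi_pa"]]),
                   trace = trace)
  final <- infer(model$final,
                 c(mental = val(mental), physical = physical,
                   burnout = val(burnout)),
                 trace = trace)

  res <- list(normalized = normalized,
              module_mental = val(mental),
              module_physical = physical,
              module_burnout = val(burnout),
              plus_score = val(final))
  if (trace) {
    res$trace <- list(tier1 = tier1, mental = mental, burnout = burnout,
                      final = final)
  }
  structure(res, class = "plus_result")
}

#' @export
print.plus_result <- function(x, ...) {
  cat("PLUS evaluation\n")
  cat("  normalized:", paste(sprintf("%s=%.3f", names(x$normalized),
                                     x$normalized), collapse = " "), "\n")
  cat(sprintf("  modules: mental=%.3f physical=%.3f burnout=%.3f\n",
              x$module_mental, x$module_physical, x$module_burnout))
  cat(sprintf("  PLUS score: %.3f\n", x$plus_score))
  invisible(x)
}

#' Extrema of the PLUS score over an exhaustive input grid
#'
#' Evaluates the full hierarchy at every combination of \code{n_levels}
#' evenly spaced levels per scale (including both endpoints of each legal
#' range) and returns the minimum and maximum PLUS score. Tier-1 and tier-2
#' results are memoized over the grid, so the default 15,625-point sweep
#' runs in seconds.
#'
#' @param n_levels Levels per input axis (default 5).
#' @param model A \code{plus_model}.
#' @return List with \code{min}, \code{max} and \code{n} (grid size).
#' @export
plus_grid_range <- function(n_levels = 5, model = plus_default_model()) {
  stopifnot(n_levels >= 2)
  tab <- .plus_scale_table()
  ids <- names(model$normalizers)
  norm_levels <- lapply(ids, function(id) {
    raw <- seq(tab[[id]]$domain[1], tab[[id]]$domain[2], length.out = n_levels)
    vapply(raw, function(x) plus_normalize(id, x, model), numeric(1))
  })
  names(norm_levels) <- ids

  mental <- outer(seq_len(n_levels), seq_len(n_levels),
                  Vectorize(function(i, j)
                    infer(model$module_mental,
                          c(pss10 = norm_levels$pss10[i],
                            swls = norm_levels$swls[j]))))
  burn_idx <- expand.grid(e = seq_len(n_levels), d = seq_len(n_levels),
                          p = seq_len(n_levels))
  burnout <- vapply(seq_len(nrow(burn_idx)), function(k)
    infer(model$module_burnout,
          c(mbi_ee = norm_levels$mbi_ee[burn_idx$e[k]],
            mbi_dp = norm_levels$mbi_dp[burn_idx$d[k]],
            mbi_pa = norm_levels$mbi_pa[burn_idx$p[k]])), numeric(1))

  triples <- expand.grid(m = as.vector(mental), p = norm_levels$nmq,
                         b = burnout)
  uniq <- unname(unique(round(as.matrix(triples), 12)))
  finals <- vapply(seq_len(nrow(uniq)), function(k)
    infer(model$final, c(mental = uniq[k, 1], physical = uniq[k, 2],
                         burnout = uniq[k, 3])), numeric(1))
  list(min = min(finals), max = max(finals), n = nrow(triples))
}
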