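# Model definition files: the whole hierarchy (every set parameter and every
# rule) ships as data, so a deployment can audit or adapt the model without
# touching code. JSON is the default (full double precision); YAML is
# accepted for hand-edited definitions.

.var_to_list <- function(v) {
  list(name = v$name, domain = v$domain,
       sets = lapply(v$sets, function(s)
         list(label = s$label, params = c(s$l, s$k1, s$k2, s$r))))
}

.var_from_list <- function(x, overshoot = 1) {
  fuzzy_variable(x$name, as.numeric(unlist(x$domain)),
                 lapply(x$sets, function(s) {
                   p <- as.numeric(unlist(s$params))
                   fuzzy_trapezoid(p[1], p[2], p[3], p[4], label = s$label)
                 }), overshoot = overshoot)
}

.system_to_list <- function(sys) {
  list(inputs = lapply(unname(sys$inputs), .var_to_list),
       output = .var_to_list(sys$output),
       rules = lapply(sys$rules, function(rl)
         list(if_ = as.list(rl$antecedent), then_ = rl$consequent)),
       operators = unclass(sys$operators),
       defuzz_domain = sys$defuzz_domain)
}

.system_from_list <- function(x) {
  ops <- do.call(operator_config, lapply(x$operators, as.character))
  mamdani_system(
    inputs = lapply(x$inputs, .var_from_list),
    output = .var_from_list(x$output),
    rules = lapply(x$rules, function(rl) {
      ant <- vapply(rl$if_, as.character, character(1))
      fuzzy_rule(ant, as.character(rl$then_))
    }),
    operators = ops,
    defuzz_domain = as.numeric(unlist(x$defuzz_domain))
  )
}

#' Serialize a PLUS model definition to a config file
#'
#' Writes every variable, set parameter, rule and operator of the hierarchy
#' to JSON (default, full double precision) or YAML, chosen by file
#' extension. \code{\link{read_model_config}} reconstructs a model whose
#' outputs are identical to the original.
#'
#' @param model A \code{plus_model}.
#' @param path Output path ending in \code{.json}, \code{.yaml} or
#'   \code{.yml}.
#' @return \code{path}, invisibly.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "plus_model"))
  cfg <- list(
    model = "plus",
    normalizers = lapply(model$normalizers, .system_to_list),
    module_mental = .system_to_list(model$module_mental),
    module_burnout = .system_to_list(model$module_burnout),
    final = .system_to_list(model$final)
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    writeLines(yaml::as.yaml(cfg, precision = 17), path)
  } else {
    # 17 significant digits: doubles survive the round-trip bit-identically
    jsonlite::write_json(cfg, path, digits = I(17), auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Load a PLUS model definition from a config file
#'
#' @param path Path to a JSON or YAML model definition written by
#'   \code{\link{write_model_config}} (or hand-authored in the same schema).
#' @return A \code{plus_model}.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path)
  }
  if (!identical(cfg$model, "plus")) {
    stop("not a PLUS model definition (missing model: plus header)",
         call. = FALSE)
  }
  structure(list(
    normalizers = lapply(cfg$normalizers, .system_from_list),
    module_mental = .system_from_list(cfg$module_mental),
    module_burnout = .system_from_list(cfg$module_burnout),
    final = .system_from_list(cfg$final)
  ), class = "plus_model")
}

#' Sanity-check a model definition
#'
#' Structural checks plus quick behavioural properties: Ruspini partition
#' sums on a grid for every input variable, boundary normalization of each
#' scale's best raw score, and module mirror symmetry on a few points.
#'
#' @param model A \code{plus_model}.
#' @param n_grid Grid density for the partition check.
#' @return \code{TRUE} invisibly; stops with a message on failure.
#' @export
validate_model <- function(model, n_grid = 501) {
  stopifnot(inherits(model, "plus_model"))
  for (sys in model$normalizers) {
    v <- sys$inputs[[1]]
    xs <- seq(v$domain[1], v$domain[2], length.out = n_grid)
    sums <- rowSums(vapply(v$sets, trapezoid_membership, numeric(length(xs)),
                           x = xs))
    if (max(abs(sums - 1)) > 1e-9) {
      stop("input partition of '", v$name, "' is not a Ruspini partition",
           call. = FALSE)
    }
  }
  for (p in list(c(0.2, 0.7, 0.4), c(0, 1, 0.5))) {
    f <- infer(model$final, setNames(p, names(model$final$inputs)))
    g <- infer(model$final, setNames(1 - p, names(model$final$inputs)))
    if (abs(f + g - 1) > 1e-9) {
      stop("final tier violates mirror symmetry", call. = FALSE)
    }
  }
  invisible(TRUE)
}
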