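#' Reference PLUS outcomes for two occupational cohorts
#'
#' The 120 published PLUS model outcomes for the original study cohorts:
#' 20 physiotherapists (\code{"group1"}) and 20 IT professionals
#' (\code{"group2"}), each evaluated at three timepoints (before the
#' COVID-19 pandemic, during its second year, and during the war in the
#' neighbouring country). The raw questionnaire answers behind these scores
#' were never released, so the outcomes serve as a fixture for the
#' group-summary and trend utilities, not as a target the model can be
#' re-run against.
#'
#' @return A data frame with columns \code{subject} (1--20), \code{group}
#'   (\code{"group1"}/\code{"group2"}), \code{timepoint}
#'   (\code{"t1"}/\code{"t2"}/\code{"t3"}) and \code{plus_score}.
#' @export
reference_outcomes <- function() {
  g1 <- rbind(
    c(0.297, 0.236, 0.222), c(0.428, 0.339, 0.244), c(0.445, 0.406, 0.191),
    c(0.426, 0.395, 0.361), c(0.324, 0.315, 0.182), c(0.391, 0.391, 0.241),
    c(0.482, 0.445, 0.278), c(0.361, 0.286, 0.210), c(0.500, 0.406, 0.247),
    c(0.391, 0.376, 0.206), c(0.406, 0.350, 0.217), c(0.445, 0.322, 0.200),
    c(0.445, 0.406, 0.297), c(0.445, 0.253, 0.213), c(0.324, 0.315, 0.188),
    c(0.468, 0.445, 0.322), c(0.445, 0.293, 0.221), c(0.352, 0.338, 0.291),
    c(0.406, 0.297, 0.195), c(0.445, 0.400, 0.235))
  g2 <- rbind(
    c(0.500, 0.500, 0.500), c(0.500, 0.500, 0.500), c(0.500, 0.500, 0.500),
    c(0.500, 0.428, 0.462), c(0.500, 0.462, 0.500), c(0.500, 0.361, 0.428),
    c(0.500, 0.500, 0.500), c(0.500, 0.500, 0.500), c(0.462, 0.406, 0.500),
    c(0.500, 0.380, 0.462), c(0.462, 0.428, 0.500), c(0.500, 0.406, 0.462),
    c(0.500, 0.428, 0.462), c(0.594, 0.594, 0.555), c(0.500, 0.462, 0.500),
    c(0.500, 0.477, 0.500), c(0.500, 0.428, 0.500), c(0.500, 0.462, 0.500),
    c(0.500, 0.428, 0.500), c(0.500, 0.500, 0.500))
  mk <- function(m, grp) data.frame(
    subject = rep(seq_len(nrow(m)), each = 3L),
    group = grp,
    timepoint = rep(c("t1", "t2", "t3"), nrow(m)),
    plus_score = as.vector(t(m)))
  rbind(mk(g1, "group1"), mk(g2, "group2"))
}
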