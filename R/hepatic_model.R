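#' The hepatic glucose/lipid metabolism logical model
#'
#' Loads the packaged multi-valued logical model of hepatic glucose and
#' lipid metabolism: 24 components (3 inputs: glucose, glucagon, fatty
#' acids; 5 metabolic program outputs: gluconeogenesis, glycolysis,
#' lipogenesis, lipolysis, adipogenesis; 16 internal signaling and
#' transcription components) connected by 37 signed interactions, with
#' Pgc1a as the single ternary component (levels 0/1/2). The rule set is
#' a curated reconstruction of canonical hepatic insulin and glucagon
#' signaling; each rule in the fixture file carries a provenance note.
#'
#' @param include_mir34a also add \code{miR34a_5p} as an optional Boolean
#'   input inhibiting Irs2 (off by default; when added, the model gains
#'   one component and two interactions and the Irs2 rule requires the
#'   miRNA to be absent).
#' @return a \code{\link{logical_model}}.
#' @export
#' @examples
#' m <- hepatic_model()
#' nrow(m$components)
hepatic_model <- function(include_mir34a = FALSE) {
  path <- system.file("extdata", "hepatic_model.json",
                      package = "mirmaster", mustWork = TRUE)
  model <- suppressMessages(load_model(path))
  if (include_mir34a) {
    comps <- rbind(model$components,
                   data.frame(name = "miR34a_5p", max_level = 1L,
                              role = "input", stringsAsFactors = FALSE))
    inter <- rbind(model$interactions,
                   data.frame(source = "miR34a_5p", target = "Irs2",
                              sign = "inhibition", threshold = 1L,
                              stringsAsFactors = FALSE))
    rules <- lapply(model$rules, function(r) {
      list(target = r$target,
           clauses = lapply(r$clauses, function(cl) {
             list(level = cl$level, when = cl$when)
           }),
           note = r$note)
    })
    rules[["Irs2"]] <- list(
      target = "Irs2",
      expression = "Insr>=1 AND NOT miR34a_5p>=1",
      note = "miR-34a-5p post-transcriptionally represses Irs2")
    model <- logical_model(comps, inter, unname(rules))
  }
  model
}

#' The four packaged simulation environments
#'
#' Input assignments and perturbations for the context-dependent
#' stable-state analysis of \code{\link{hepatic_model}}:
#' \describe{
#'   \item{fed}{glucose high, glucagon and fatty acids low (calibration
#'     control: insulin/Irs2/Akt signaling on, glycolysis, lipogenesis
#'     and adipogenesis active, gluconeogenesis off).}
#'   \item{fasting}{glucose low, glucagon and fatty acids high
#'     (lipolysis and gluconeogenesis active).}
#'   \item{fed_pgc1a_ko}{fed inputs with Pgc1a knocked out.}
#'   \item{fasting_pgc1a_ko}{fasting inputs with Pgc1a knocked out
#'     (lipolysis on, but neither gluconeogenesis nor adipogenesis).}
#'   \item{fasting_irs2_ectopic}{fasting inputs with Irs2 clamped to its
#'     maximum (gluconeogenesis off, glycolysis and lipogenesis on,
#'     Pgc1a at its intermediate level).}
#' }
#'
#' @return named list of environments suitable for
#'   \code{\link{simulate_environments}}.
#' @export
hepatic_environments <- function() {
  fed <- c(glucose = 1L, glucagon = 0L, FA = 0L)
  fasting <- c(glucose = 0L, glucagon = 1L, FA = 1L)
  list(
    fed = list(inputs = fed),
    fasting = list(inputs = fasting),
    fed_pgc1a_ko = list(inputs = fed, perturbation = c(Pgc1a = 0L)),
    fasting_pgc1a_ko = list(inputs = fasting,
                            perturbation = c(Pgc1a = 0L)),
    fasting_irs2_ectopic = list(inputs = fasting,
                                perturbation = c(Irs2 = 1L))
  )
}

#' Expected activation patterns for the packaged environments
#'
#' The component levels each packaged environment must exhibit in its
#' stable state; used by the regression tests and the acceptance script.
#' Only the constrained components are listed.
#'
#' @return named list: environment -> named integer vector of required
#'   levels.
#' @export
hepatic_expected_patterns <- function() {
  list(
    fed = c(insulin = 1L, Irs2 = 1L, Akt = 1L, glycolysis = 1L,
            lipogenesis = 1L, adipogenesis = 1L, gluconeogenesis = 0L),
    fasting = c(lipolysis = 1L, gluconeogenesis = 1L),
    fed_pgc1a_ko = c(glycolysis = 1L, lipogenesis = 1L),
    fasting_pgc1a_ko = c(lipolysis = 1L, gluconeogenesis = 0L,
                         adipogenesis = 0L, Irs2 = 0L),
    fasting_irs2_ectopic = c(gluconeogenesis = 0L, glycolysis = 1L,
                             lipogenesis = 1L, Pgc1a = 1L)
  )
}
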