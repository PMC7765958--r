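## Multi-valued logical models: regulatory graphs with threshold rules,
## synchronous update, clamping perturbations, exhaustive stable-state
## (fixed point) enumeration. Rules are written in a restricted grammar
## over literals `name>=k`, operators AND / OR / NOT (or & | !), and
## parentheses; a multi-level target carries an ordered clause list
## (level, condition), first match wins, default level 0.

RULE_TOKEN_RE <- "^\\s*(\\(|\\)|AND|OR|NOT|&&?|\\|\\|?|!|[A-Za-z][A-Za-z0-9_.]*\\s*>=\\s*[0-9]+)"

parse_rule_expression <- function(text) {
  if (!nzchar(trimws(text))) stop("empty rule expression")
  rest <- text
  out <- character(0)
  refs <- character(0)
  while (nzchar(trimws(rest))) {
    m <- regexpr(RULE_TOKEN_RE, rest, perl = TRUE)
    if (m == -1L) stop("cannot parse rule expression near: '", rest, "'")
    tok <- trimws(regmatches(rest, m))
    rest <- substring(rest, m + attr(m, "match.length"))
    r_tok <- switch(tok,
                    "AND" = "&", "&&" = "&", "&" = "&",
                    "OR" = "|", "||" = "|", "|" = "|",
                    "NOT" = "!", "!" = "!",
                    "(" = "(", ")" = ")",
                    { # literal name >= k
                      parts <- strsplit(tok, ">=")[[1L]]
                      nm <- trimws(parts[[1L]])
                      refs <- c(refs, nm)
                      paste0("(`", nm, "` >= ", trimws(parts[[2L]]), ")")
                    })
    out <- c(out, r_tok)
  }
  expr <- tryCatch(str2lang(paste(out, collapse = " ")),
                   error = function(e) stop("malformed rule expression: ",
                                            text))
  list(expr = expr, refs = unique(refs), text = text)
}

normalize_rule <- function(rule) {
  ## accepted forms: list(target=, expression=) for a Boolean rule
  ## (level = 1 when true), or list(target=, clauses=list(list(level=,
  ## when=), ...)) for multi-valued targets
  if (!is.null(rule$expression)) {
    clauses <- list(list(level = 1L, when = rule$expression))
  } else if (!is.null(rule$clauses)) {
    clauses <- rule$clauses
  } else stop("rule for '", rule$target,
              "' needs an 'expression' or 'clauses'")
  parsed <- lapply(clauses, function(cl) {
    if (is.null(cl$level) || is.null(cl$when)) {
      stop("each clause needs 'level' and 'when' (target ", rule$target, ")")
    }
    p <- parse_rule_expression(cl$when)
    list(level = as.integer(cl$level), when = cl$when, expr = p$expr,
         refs = p$refs)
  })
  list(target = rule$target, clauses = parsed,
       refs = unique(unlist(lapply(parsed, `[[`, "refs"))),
       note = rule$note %||% NULL)
}

#' Construct and validate a multi-valued logical model
#'
#' @param components data.frame with columns \code{name},
#'   \code{max_level} (1 = Boolean, 2 = ternary), \code{role}
#'   (\code{input}, \code{internal} or \code{output}).
#' @param interactions data.frame with columns \code{source},
#'   \code{target}, \code{sign} (\code{activation}/\code{inhibition}) and
#'   optionally \code{threshold} (minimal source level activating the
#'   interaction, default 1).
#' @param rules list of rules; each rule is a list with \code{target} and
#'   either \code{expression} (Boolean) or \code{clauses} (ordered list of
#'   \code{list(level, when)}; first matching clause sets the level,
#'   default 0). Conditions use the grammar \code{name>=k}, \code{AND},
#'   \code{OR}, \code{NOT}, parentheses.
#' @return object of class \code{logical_model}.
#' @export
logical_model <- function(components, interactions, rules) {
  components <- as.data.frame(components, stringsAsFactors = FALSE)
  interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "max_level", "role") %in% names(components)),
            all(c("source", "target", "sign") %in% names(interactions)) ||
              nrow(interactions) == 0L)
  components$max_level <- as.integer(components$max_level)
  if (is.null(interactions$threshold)) interactions$threshold <-
      rep(1L, nrow(interactions))
  interactions$threshold <- as.integer(interactions$threshold)

  nm <- components$name
  if (anyDuplicated(nm)) stop("duplicated component names")
  if (!all(components$max_level %in% 1:2)) {
    stop("max_level must be 1 (Boolean) or 2 (ternary)")
  }
  if (!all(components$role %in% c("input", "internal", "output"))) {
    stop("role must be input, internal or output")
  }
  if (nrow(interactions)) {
    bad <- setdiff(c(interactions$source, interactions$target), nm)
    if (length(bad)) stop("interaction references undeclared component(s): ",
                          paste(unique(bad), collapse = ", "))
    if (!all(interactions$sign %in% c("activation", "inhibition"))) {
      stop("interaction sign must be activation or inhibition")
    }
    roles <- setNames(components$role, nm)
    maxl <- setNames(components$max_level, nm)
    if (any(roles[interactions$target] == "input")) {
      stop("input components cannot have incoming interactions")
    }
    if (any(roles[interactions$source] == "output")) {
      stop("output components cannot have outgoing interactions")
    }
    over <- interactions$threshold > maxl[interactions$source]
    if (any(over)) stop("interaction threshold exceeds source max_level for ",
                        paste(interactions$source[over], collapse = ", "))
  }

  rules <- lapply(rules, normalize_rule)
  names(rules) <- vapply(rules, `[[`, "", "target")
  roles <- setNames(components$role, nm)
  maxl <- setNames(components$max_level, nm)
  for (r in rules) {
    if (!r$target %in% nm) stop("rule targets undeclared component: ",
                                r$target)
    if (roles[[r$target]] == "input") {
      stop("input component '", r$target, "' cannot carry a rule")
    }
    declared <- interactions$source[interactions$target == r$target]
    extra <- setdiff(r$refs, declared)
    if (length(extra)) {
      stop("rule for '", r$target, "' references regulator(s) without a ",
           "declared interaction: ", paste(extra, collapse = ", "))
    }
    for (cl in r$clauses) {
      if (cl$level < 0L || cl$level > maxl[[r$target]]) {
        stop("clause level out of range for '", r$target, "'")
      }
    }
  }
  missing_rules <- setdiff(nm[roles != "input"], names(rules))
  if (length(missing_rules)) {
    stop("non-input component(s) without a rule: ",
         paste(missing_rules, collapse = ", "))
  }
  structure(list(components = components, interactions = interactions,
                 rules = rules),
            class = "logical_model")
}

#' @export
print.logical_model <- function(x, ...) {
  cat("logical_model:", nrow(x$components), "components,",
      nrow(x$interactions), "interactions\n")
  invisible(x)
}

#' Load a logical model from its JSON description
#'
#' The file holds \code{components}, \code{interactions} and \code{rules}
#' as documented in \code{\link{logical_model}}; \code{note} fields are
#' preserved for provenance.
#'
#' @param path path to the model JSON file.
#' @return a validated \code{logical_model}; component and interaction
#'   counts are reported via a message.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  comps <- do.call(rbind, lapply(doc$components, function(cc) {
    data.frame(name = cc$name, max_level = cc$max_level %||% 1L,
               role = cc$role %||% "internal", stringsAsFactors = FALSE)
  }))
  inter <- if (length(doc$interactions)) {
    do.call(rbind, lapply(doc$interactions, function(ii) {
      data.frame(source = ii$source, target = ii$target, sign = ii$sign,
                 threshold = ii$threshold %||% 1L, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(source = character(0), target = character(0),
               sign = character(0), threshold = integer(0),
               stringsAsFactors = FALSE)
  }
  model <- logical_model(comps %||% data.frame(name = character(0),
                                               max_level = integer(0),
                                               role = character(0)),
                         inter, doc$rules %||% list())
  message("loaded logical model: ", nrow(model$components), " components, ",
          nrow(model$interactions), " interactions")
  model
}

#' Save a logical model to JSON
#'
#' Inverse of \code{\link{load_model}}; a load-save-load round trip
#' reproduces the model.
#'
#' @param model a \code{logical_model}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
save_model <- function(model, path) {
  doc <- list(
    components = lapply(seq_len(nrow(model$components)), function(i) {
      as.list(model$components[i, ])
    }),
    interactions = lapply(seq_len(nrow(model$interactions)), function(i) {
      as.list(model$interactions[i, ])
    }),
    rules = lapply(model$rules, function(r) {
      out <- list(target = r$target,
                  clauses = lapply(r$clauses, function(cl) {
                    list(level = cl$level, when = cl$when)
                  }))
      if (!is.null(r$note)) out$note <- r$note
      out
    })
  )
  names(doc$rules) <- NULL
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

eval_clauses <- function(rule, env_list, n_rows) {
  level <- rep.int(0L, n_rows)
  undecided <- rep.int(TRUE, n_rows)
  for (cl in rule$clauses) {
    hit <- undecided & rep_len(eval(cl$expr, env_list), n_rows)
    level[hit] <- cl$level
    undecided <- undecided & !hit
  }
  level
}

check_state <- function(model, state) {
  nm <- model$components$name
  if (!setequal(names(state), nm)) {
    stop("state must assign a level to every component")
  }
  state <- state[nm]
  maxl <- model$components$max_level
  if (any(state < 0L | state > maxl)) stop("state level out of range")
  storage.mode(state) <- "integer"
  state
}

#' Synchronous update of a model state
#'
#' Every non-input, non-clamped component is set to the value of its rule
#' evaluated on the given state; inputs and clamped components are left
#' unchanged.
#'
#' @param model a \code{logical_model}.
#' @param state named integer vector, component -> level.
#' @param perturbation optional named vector of clamped levels
#'   (knockout = 0, ectopic = max_level).
#' @return the image state (named integer vector).
#' @export
update_state <- function(model, state, perturbation = NULL) {
  state <- check_state(model, state)
  env_list <- as.list(state)
  out <- state
  roles <- setNames(model$components$role, model$components$name)
  for (nm in names(model$rules)) {
    if (roles[[nm]] == "input") next
    out[[nm]] <- eval_clauses(model$rules[[nm]], env_list, 1L)
  }
  if (!is.null(perturbation)) {
    bad <- setdiff(names(perturbation), model$components$name)
    if (length(bad)) stop("perturbation references unknown component(s): ",
                          paste(bad, collapse = ", "))
    out[names(perturbation)] <- as.integer(perturbation)
  }
  out
}

#' Exhaustive stable states of a logical model
#'
#' Enumerates all assignments of the free components (non-input,
#' non-clamped, non-sink) and returns the states fixed under
#' \code{\link{update_state}}. Output components that are pure sinks are
#' evaluated functionally rather than enumerated, shrinking the search
#' space. States are returned in lexicographic order of the component
#' levels (components alphabetically).
#'
#' @param model a \code{logical_model}.
#' @param inputs named vector assigning a level to every input component.
#' @param perturbation optional named vector of clamps.
#' @param max_states cap on the enumerated space (default 2^24); above it
#'   an error advises reducing the model or clamping components.
#' @return list of stable states (named integer vectors), possibly empty.
#' @export
stable_states <- function(model, inputs, perturbation = NULL,
                          max_states = 2^24) {
  comps <- model$components
  nm <- comps$name
  roles <- setNames(comps$role, nm)
  maxl <- setNames(comps$max_level, nm)

  input_names <- nm[roles == "input"]
  if (!setequal(intersect(names(inputs), input_names), input_names)) {
    stop("inputs must assign a level to every input component: ",
         paste(input_names, collapse = ", "))
  }
  clamp_names <- character(0)
  if (!is.null(perturbation)) {
    bad <- setdiff(names(perturbation), nm)
    if (length(bad)) stop("perturbation references unknown component(s): ",
                          paste(bad, collapse = ", "))
    clamp_names <- names(perturbation)
  }
  fixed <- c(as.list(inputs[input_names]),
             as.list(perturbation %||% integer(0)))
  ## inputs may additionally be clamped; clamps win
  fixed <- fixed[!duplicated(names(fixed), fromLast = TRUE)]

  sink_names <- setdiff(nm[roles == "output"], c(clamp_names, input_names))
  free <- setdiff(nm, c(names(fixed), sink_names))

  sizes <- maxl[free] + 1
  total <- prod(sizes)
  if (total > max_states) {
    stop("free state space (", format(total, big.mark = ","), ") exceeds ",
         "max_states; clamp components or reduce the model")
  }

  grid <- if (length(free)) {
    as.list(do.call(expand.grid, lapply(sizes, function(s) 0:(s - 1))))
  } else list()
  n_rows <- if (length(free)) length(grid[[1L]]) else 1L
  cols <- c(lapply(fixed, function(v) rep.int(as.integer(v), n_rows)),
            lapply(grid, as.integer))
  names(cols) <- c(names(fixed), free)

  ## sinks evaluated functionally (their rules never reference outputs,
  ## outputs having no outgoing interactions)
  for (s in sink_names) {
    cols[[s]] <- eval_clauses(model$rules[[s]], cols, n_rows)
  }

  ## fixed-point condition on every non-clamped, non-input component
  ok <- rep.int(TRUE, n_rows)
  for (comp in setdiff(nm, c(input_names, clamp_names, sink_names))) {
    ok <- ok & (eval_clauses(model$rules[[comp]], cols, n_rows) ==
                  cols[[comp]])
    if (!any(ok)) break
  }
  idx <- which(ok)
  states <- lapply(idx, function(i) {
    setNames(vapply(nm, function(cn) cols[[cn]][[i]], integer(1)), nm)
  })
  ord_names <- sort(nm)
  if (length(states) > 1L) {
    key <- vapply(states, function(s) paste(s[ord_names], collapse = ","),
                  character(1))
    states <- states[order(key)]
  }
  states
}

#' Simulate a table of environments (inputs plus perturbations)
#'
#' Runs \code{\link{stable_states}} for each environment and assembles a
#' per-environment table of component levels.
#'
#' @param model a \code{logical_model}.
#' @param environments named list; each element is a list with
#'   \code{inputs} (named vector over the input components) and optional
#'   \code{perturbation} (named clamp vector).
#' @return object of class \code{environment_report}: list with
#'   \code{table} (data.frame: environment, state index, one column per
#'   component) and \code{states} (nested list).
#' @export
simulate_environments <- function(model, environments) {
  stopifnot(length(names(environments)) == length(environments))
  nm <- model$components$name
  all_states <- lapply(environments, function(env) {
    stable_states(model, env$inputs, env$perturbation %||% NULL)
  })
  rows <- list()
  for (e in names(environments)) {
    sts <- all_states[[e]]
    if (!length(sts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        environment = e, state = NA_integer_,
        as.list(setNames(rep(NA_integer_, length(nm)), nm)),
        check.names = FALSE, stringsAsFactors = FALSE)
    } else {
      for (i in seq_along(sts)) {
        rows[[length(rows) + 1L]] <- data.frame(
          environment = e, state = i, as.list(sts[[i]]),
          check.names = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, states = all_states),
            class = "environment_report")
}

#' @export
print.environment_report <- function(x, ...) {
  print(x$table)
  invisible(x)
}

#' Write an environment report as TSV, blanks for level 0
#'
#' Mirrors the usual tabular display of context-dependent stable states:
#' rows are environments, columns components, empty cells inactive
#' components.
#'
#' @param report an \code{environment_report}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_environment_report <- function(report, path) {
  tab <- report$table
  for (j in seq(3L, ncol(tab))) {
    v <- tab[[j]]
    tab[[j]] <- ifelse(is.na(v) | v == 0L, "", as.character(v))
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a logical model as SBML-qual
#'
#' Minimal SBML Level 3 qual serialization (qualitative species with max
#' levels, transitions with sign inputs) for interoperability with
#' logical-modeling tools.
#'
#' @param model a \code{logical_model}.
#' @param path output .sbml path.
#' @return \code{path}, invisibly.
#' @export
write_sbml_qual <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:qual" = "http://www.sbml.org/sbml/level3/version1/qual/version1",
    level = "3", version = "1")
  mdl <- xml2::xml_add_child(doc, "model", id = "logical_model")
  lqs <- xml2::xml_add_child(mdl, "qual:listOfQualitativeSpecies")
  for (i in seq_len(nrow(model$components))) {
    cc <- model$components[i, ]
    xml2::xml_add_child(lqs, "qual:qualitativeSpecies",
                        "qual:id" = cc$name,
                        "qual:maxLevel" = as.character(cc$max_level),
                        "qual:constant" = if (cc$role == "input") "true"
                                          else "false")
  }
  lot <- xml2::xml_add_child(mdl, "qual:listOfTransitions")
  for (target in names(model$rules)) {
    tr <- xml2::xml_add_child(lot, "qual:transition",
                              "qual:id" = paste0("tr_", target))
    lin <- xml2::xml_add_child(tr, "qual:listOfInputs")
    inter <- model$interactions[model$interactions$target == target, ,
                                drop = FALSE]
    for (i in seq_len(nrow(inter))) {
      xml2::xml_add_child(lin, "qual:input",
                          "qual:qualitativeSpecies" = inter$source[i],
                          "qual:sign" = if (inter$sign[i] == "activation")
                            "positive" else "negative",
                          "qual:thresholdLevel" =
                            as.character(inter$threshold[i]))
    }
    lout <- xml2::xml_add_child(tr, "qual:listOfOutputs")
    xml2::xml_add_child(lout, "qual:output",
                        "qual:qualitativeSpecies" = target,
                        "qual:transitionEffect" = "assignmentLevel")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
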