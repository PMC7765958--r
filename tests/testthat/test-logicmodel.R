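toggle_model <- function() {
  logical_model(
    components = data.frame(name = c("A", "B"), max_level = 1L,
                            role = "internal", stringsAsFactors = FALSE),
    interactions = data.frame(source = c("A", "B"), target = c("B", "A"),
                              sign = "inhibition", threshold = 1L,
                              stringsAsFactors = FALSE),
    rules = list(list(target = "A", expression = "NOT B>=1"),
                 list(target = "B", expression = "NOT A>=1")))
}

test_that("model validation enforces roles, levels and rule references", {
  comps <- data.frame(name = c("in1", "x", "out1"),
                      max_level = c(1L, 2L, 1L),
                      role = c("input", "internal", "output"),
                      stringsAsFactors = FALSE)
  inter <- data.frame(source = c("in1", "x"), target = c("x", "out1"),
                      sign = "activation", threshold = c(1L, 2L),
                      stringsAsFactors = FALSE)
  rules <- list(list(target = "x",
                     clauses = list(list(level = 2, when = "in1>=1"))),
                list(target = "out1", expression = "x>=2"))
  m <- logical_model(comps, inter, rules)
  expect_identical(nrow(m$components), 3L)

  expect_error(logical_model(comps, inter,
                             c(rules[1], list(list(target = "out1",
                                                   expression = "zz>=1")))),
               "without a declared interaction|undeclared")
  bad_inter <- within(inter, target[1] <- "in1")
  expect_error(logical_model(comps, bad_inter, rules), "input components")
  expect_error(logical_model(comps, within(inter, threshold[1] <- 5L),
                             rules), "threshold exceeds")
  expect_error(logical_model(comps, inter, rules[1]), "without a rule")
  # an empty model is valid
  empty <- logical_model(comps[0, ], inter[0, ], list())
  expect_identical(nrow(empty$components), 0L)
})

test_that("synchronous update follows rules, inputs and clamps", {
  comps <- data.frame(name = c("A", "B"), max_level = 1L,
                      role = c("input", "internal"),
                      stringsAsFactors = FALSE)
  inter <- data.frame(source = "A", target = "B", sign = "activation",
                      threshold = 1L, stringsAsFactors = FALSE)
  m <- logical_model(comps, inter,
                     list(list(target = "B", expression = "A>=1")))
  s <- update_state(m, c(A = 1L, B = 0L))
  expect_identical(s, c(A = 1L, B = 1L))
  # fixed point returned unchanged
  expect_identical(update_state(m, s), s)
  # inputs never move; clamps override rules
  expect_identical(update_state(m, c(A = 0L, B = 1L))[["A"]], 0L)
  expect_identical(update_state(m, c(A = 1L, B = 0L),
                                perturbation = c(B = 0L))[["B"]], 0L)
  expect_error(update_state(m, c(A = 3L, B = 0L)), "out of range")
})

test_that("random models update identically to a truth-table oracle", {
  for (seed in 1:10) {
    m <- random_boolean_model(n_comp = 6L, n_inputs = 2L, seed = seed)
    nm <- m$components$name
    roles <- setNames(m$components$role, nm)
    set.seed(seed + 100)
    for (i in 1:20) {
      st <- setNames(sample(0:1, length(nm), replace = TRUE), nm)
      got <- update_state(m, st)
      # naive single-component evaluation by literal substitution
      want <- st
      for (target in nm[roles != "input"]) {
        rule <- m$rules[[target]]
        val <- 0L
        for (cl in rule$clauses) {
          ok <- eval(cl$expr, as.list(st))
          if (ok) { val <- cl$level; break }
        }
        want[[target]] <- val
      }
      expect_identical(got, want)
    }
  }
})

test_that("stable states match hand enumeration and the brute-force scan", {
  # mutual inhibition: exactly the two exclusive states are stable
  tg <- toggle_model()
  sts <- stable_states(tg, inputs = integer(0))
  expect_length(sts, 2L)
  expect_identical(sts[[1]], c(A = 0L, B = 1L))
  expect_identical(sts[[2]], c(A = 1L, B = 0L))

  # simple input-driven chain has the single propagated state
  comps <- data.frame(name = c("A", "B"), max_level = 1L,
                      role = c("input", "internal"),
                      stringsAsFactors = FALSE)
  chain <- logical_model(
    comps,
    data.frame(source = "A", target = "B", sign = "activation",
               threshold = 1L, stringsAsFactors = FALSE),
    list(list(target = "B", expression = "A>=1")))
  expect_identical(stable_states(chain, c(A = 1L)),
                   list(c(A = 1L, B = 1L)))

  # every returned state is independently re-checked as a fixed point,
  # and the fast enumerator agrees with the full-space scan
  for (seed in 11:22) {
    m <- random_boolean_model(n_comp = sample(4:9, 1), n_inputs = 1L,
                              seed = seed)
    inputs <- setNames(sample(0:1, 1), m$components$name[1])
    fast <- stable_states(m, inputs)
    slow <- bf_stable_states(m, inputs)
    key <- function(l) sort(vapply(l, function(s) {
      paste(s[sort(names(s))], collapse = ",")
    }, character(1)))
    expect_identical(key(fast), key(slow))
    for (s in fast) expect_identical(update_state(m, s), s)
  }
})

test_that("clamping respects stable structure and unknown names fail", {
  tg <- toggle_model()
  # clamping a component at its level in a stable state keeps that state
  sts <- stable_states(tg, integer(0))
  for (s in sts) {
    clamped <- stable_states(tg, integer(0),
                             perturbation = s["A"])
    key <- vapply(clamped, paste, "", collapse = ",")
    expect_true(paste(s, collapse = ",") %in% key)
  }
  expect_error(stable_states(tg, integer(0), perturbation = c(Z = 1L)),
               "unknown component")
  # clamping every component makes that assignment the unique stable state
  all_clamp <- c(A = 1L, B = 1L)
  expect_identical(stable_states(tg, integer(0), perturbation = all_clamp),
                   list(all_clamp))
  # state-space cap triggers a helpful error
  big <- random_boolean_model(n_comp = 10L, n_inputs = 1L, seed = 5)
  expect_error(stable_states(big, setNames(1L, big$components$name[1]),
                             max_states = 4), "max_states")
})

test_that("model serialization round-trips through JSON and SBML-qual exists", {
  m <- hepatic_model()
  tmp <- tempfile(fileext = ".json")
  save_model(m, tmp)
  m2 <- suppressMessages(load_model(tmp))
  expect_equal(m$components, m2$components)
  expect_equal(m$interactions, m2$interactions)
  expect_identical(lapply(m$rules, function(r) lapply(r$clauses, `[`,
                                                      c("level", "when"))),
                   lapply(m2$rules, function(r) lapply(r$clauses, `[`,
                                                       c("level", "when"))))
  sb <- tempfile(fileext = ".sbml")
  write_sbml_qual(m, sb)
  doc <- xml2::read_xml(sb)
  expect_identical(
    length(xml2::xml_find_all(doc, "//*[local-name()='qualitativeSpecies']")),
    24L)
})

test_that("the hepatic model has its documented structure and behaviors", {
  m <- hepatic_model()
  expect_identical(nrow(m$components), 24L)
  expect_identical(nrow(m$interactions), 37L)
  expect_identical(sum(m$components$role == "input"), 3L)
  expect_identical(sum(m$components$role == "output"), 5L)
  expect_identical(m$components$name[m$components$max_level == 2L], "Pgc1a")

  report <- simulate_environments(m, hepatic_environments())
  patterns <- hepatic_expected_patterns()
  for (env in names(patterns)) {
    sts <- report$states[[env]]
    expect_length(sts, 1L)
    s <- sts[[1]]
    expect_identical(s[names(patterns[[env]])], patterns[[env]])
  }
  # knockout of a pure sink leaves all other components untouched
  base <- stable_states(m, hepatic_environments()$fed$inputs)[[1]]
  ko <- stable_states(m, hepatic_environments()$fed$inputs,
                      perturbation = c(adipogenesis = 0L))[[1]]
  keep <- setdiff(names(base), "adipogenesis")
  expect_identical(ko[keep], base[keep])

  # optional miR-34a-5p extension represses Irs2 when present
  mm <- hepatic_model(include_mir34a = TRUE)
  expect_identical(nrow(mm$components), 25L)
  fed <- c(hepatic_environments()$fed$inputs, miR34a_5p = 1L)
  s <- stable_states(mm, fed)[[1]]
  expect_identical(s[["Irs2"]], 0L)
})
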