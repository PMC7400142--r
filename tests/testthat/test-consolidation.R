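test_that("the packaged workshop mapping collapses both panels to 11 main factors", {
  raw <- read.csv(fcm_example("umr_workshop_factors.csv"),
                  stringsAsFactors = FALSE)
  mapping <- read_mapping(fcm_example("umr_consolidation.yaml"))
  report <- validate_mapping(raw, mapping,
                             declared_main = attr(mapping, "main_factors"))
  expect_length(unlist(report), 0)

  main <- apply_consolidation(raw, mapping)
  expect_equal(nrow(main), 11)
  expect_setequal(main$id,
                  c("social_contacts", "housing", "health_care", "social_care",
                    "daily_activities", "residence_security", "access_education",
                    "income_security", "sociocultural_adaptation",
                    "political_climate", "german_language"))
})

test_that("keep/merge/split/exclude counting matches hand enumeration", {
  # identity case
  expect_equal(nrow(apply_consolidation(
    data.frame(label = character(), source_panel = character()), list())), 0)

  # 5 raw factors: merge 2->1, split 1->2, keep 1, exclude 1 => 4 mains
  raw <- data.frame(label = c("a", "b", "c", "d", "e"),
                    source_panel = "scientists")
  acts <- list(
    consolidation_action(c("a", "b"), "merge", "AB"),
    consolidation_action("c", "split", c("C1", "C2")),
    consolidation_action("d", "keep", "D"),
    consolidation_action("e", "exclude"))
  main <- apply_consolidation(raw, acts)
  expect_equal(nrow(main), 4)
  expect_setequal(main$name, c("AB", "C1", "C2", "D"))

  # distinct-target count equals a brute-force set union over non-excludes
  union_targets <- unique(unlist(lapply(acts, function(a)
    if (a$action == "exclude") NULL else a$main_targets)))
  expect_equal(nrow(main), length(union_targets))
})

test_that("main-factor count always equals the distinct non-exclude target set", {
  set.seed(71)
  for (rep in 1:25) {
    n <- sample(3:10, 1)
    labels <- paste0("raw", seq_len(n))
    acts <- list()
    i <- 1
    while (i <= n) {
      kind <- sample(c("keep", "merge", "split", "exclude"), 1)
      if (kind == "merge" && i < n) {
        acts <- c(acts, list(consolidation_action(labels[i:(i + 1)], "merge",
                                                  paste0("M", i))))
        i <- i + 2
      } else if (kind == "split") {
        acts <- c(acts, list(consolidation_action(labels[i], "split",
                                                  paste0("S", i, c("x", "y")))))
        i <- i + 1
      } else if (kind == "exclude") {
        acts <- c(acts, list(consolidation_action(labels[i], "exclude")))
        i <- i + 1
      } else {
        acts <- c(acts, list(consolidation_action(labels[i], "keep",
                                                  paste0("K", i))))
        i <- i + 1
      }
    }
    raw <- data.frame(label = labels, source_panel = "scientists")
    main <- apply_consolidation(raw, acts)
    brute <- unique(unlist(lapply(acts, function(a)
      if (a$action == "exclude") NULL else a$main_targets)))
    expect_equal(nrow(main), length(brute))
    # idempotence: re-consolidating the result with identity keeps is stable
    identity_acts <- lapply(main$name, function(nm)
      consolidation_action(nm, "keep", nm))
    again <- apply_consolidation(
      data.frame(label = main$name, source_panel = "scientists"),
      identity_acts)
    expect_equal(again, main)
  }
})

test_that("labels are matched case-insensitively with collapsed whitespace", {
  raw <- data.frame(label = c("  Social   Climate ", "housing"),
                    source_panel = "scientists")
  acts <- list(
    consolidation_action("social climate", "keep", "Political climate"),
    consolidation_action("HOUSING", "keep", "Housing"))
  expect_equal(nrow(apply_consolidation(raw, acts)), 2)
})

test_that("cross-panel actions naming the same target unify into one factor", {
  raw <- data.frame(label = c("Housing", "Housing"),
                    source_panel = c("scientists", "practitioners"))
  acts <- list(
    consolidation_action("Housing", "keep", "Housing", "scientists"),
    consolidation_action("Housing", "keep", "housing", "practitioners"))
  expect_equal(nrow(apply_consolidation(raw, acts)), 1)
})

test_that("coverage violations are reported and refuse to apply", {
  raw <- data.frame(label = c("Housing", "Language"),
                    source_panel = "scientists")
  only_lang <- list(consolidation_action("Language", "keep", "Language"))
  rep <- validate_mapping(raw, only_lang)
  expect_match(rep$uncovered, "housing")
  expect_error(apply_consolidation(raw, only_lang), "Housing|housing")

  both <- c(only_lang,
            list(consolidation_action("Language", "exclude")))
  rep2 <- validate_mapping(raw[2, , drop = FALSE], both)
  expect_length(rep2$multiply_covered, 1)
  expect_error(apply_consolidation(raw[2, , drop = FALSE], both),
               "more than one action")
})

test_that("malformed actions are rejected", {
  expect_error(consolidation_action("a", "split", "only-one"), "malformed")
  expect_error(consolidation_action("a", "exclude", "target"), "malformed")
  expect_error(consolidation_action(c("a", "b"), "keep", "t"), "malformed")
  expect_error(consolidation_action("a", "merge", "t"), "malformed")
  # report-returning path flags the same defect without raising
  rep <- validate_mapping(
    data.frame(label = "a", source_panel = "scientists"),
    list(list(raw_labels = "a", action = "split", main_targets = "one",
              source_panel = "scientists")))
  expect_match(rep$malformed, "split")
})
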