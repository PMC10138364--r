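test_that("gini matches its closed forms and rejects bad input", {
  expect_equal(gini(1), 0)
  expect_equal(gini(c(0.5, 0.5)), 0.5)
  expect_equal(gini(rep(0.25, 4)), 0.75)
  expect_error(gini(c(0.5, 0.4)), "sum to 1")
  expect_error(gini(c(1.2, -0.2)), "\\[0, 1\\]")
  # maximized at uniform, zero iff pure
  set.seed(51)
  for (c_ in 2:5) {
    p <- runif(c_); p <- p / sum(p)
    expect_lte(gini(p), gini(rep(1 / c_, c_)) + 1e-12)
    expect_gt(gini(p), 0 - 1e-12)
  }
})

test_that("ruleset validation fails fast on unknown variables and values", {
  expect_error(rule_set(list(list(id = "X", conditions = list(
    list(variable = "Pulse", op = "eq", value = "normal")),
    action = "monitor", priority = 1))), "unknown variable")
  expect_error(rule_set(list(list(id = "X", conditions = list(
    list(variable = "RiskC", op = "eq", value = "extreme")),
    action = "monitor", priority = 1))), "value set")
  expect_error(rule_set(list(
    list(id = "A", conditions = list(), action = "monitor", priority = 1),
    list(id = "A", conditions = list(), action = "adjust", priority = 1))),
    "duplicate")
})

test_that("rule evaluation defaults and picks by severity-first order", {
  empty <- rule_set(list())
  res <- evaluate_rules(base_state(), empty)
  expect_equal(res$action, "continue_current_treatment")
  expect_length(res$matched_ids, 0)

  rs <- load_ruleset(demo_ruleset_path())
  fall <- evaluate_rules(base_state(MoveH = "falling on the ground"), rs)
  expect_equal(fall$action, "extra_situation")
  expect_true("ES02" %in% fall$matched_ids)

  # a state matching both an adjust and an extra rule takes the extra one
  both <- evaluate_rules(base_state(Con = "unconscious",
                                    Pain = "unbearable"), rs)
  expect_equal(both$action, "extra_situation")
  expect_equal(both$matched_ids[1], "ES01")
})

test_that("rule evaluation equals a naive evaluate-all-then-pick oracle", {
  schema <- patient_state_schema()
  sev <- c(continue_current_treatment = 1, monitor = 2, adjust = 3,
           extra_situation = 4)
  set.seed(52)
  for (rep in 1:3) {
    # random ruleset: 8 rules of 1-2 uniform conditions
    raw <- lapply(1:8, function(i) {
      vars <- sample(names(schema), sample(1:2, 1))
      list(id = sprintf("R%02d", i),
           conditions = lapply(vars, function(v) {
             list(variable = v, op = "eq", value = sample(schema[[v]], 1))
           }),
           action = sample(names(sev), 1),
           priority = sample(0:5, 1))
    })
    rs <- rule_set(raw)
    states <- lapply(1:60, function(i) {
      patient_state(lapply(schema, function(vals) sample(vals, 1)))
    })
    for (st in states) {
      got <- evaluate_rules(st, rs)
      # oracle: test every rule independently, then order matches by
      # severity desc, priority desc, id asc and take the head
      matches <- Filter(function(r) {
        all(vapply(r$conditions, function(cnd) {
          identical(as.character(st[[cnd$variable]]),
                    as.character(cnd$value))
        }, logical(1)))
      }, raw)
      if (length(matches) == 0) {
        expect_equal(got$action, "continue_current_treatment")
      } else {
        ord <- order(-sev[vapply(matches, `[[`, character(1), "action")],
                     -vapply(matches, function(r) r$priority, numeric(1)),
                     vapply(matches, `[[`, character(1), "id"))
        expect_equal(got$action, matches[[ord[1]]]$action)
      }
    }
  }
})

test_that("a perfectly separable variable yields a depth-1 exact tree", {
  recs <- lapply(1:40, function(i) {
    con <- if (i %% 2 == 0) "unconscious" else "unchanged"
    list(state = base_state(Con = con),
         action = if (con == "unconscious") "extra_situation"
                  else "continue_current_treatment")
  })
  tree <- fit_tree(recs, max_depth = 3, min_samples = 6)
  expect_equal(gericare:::tree_depth(tree$root), 1)
  pred <- predict_care_tree(tree, lapply(recs, `[[`, "state"))
  expect_equal(pred, vapply(recs, `[[`, character(1), "action"))
})

test_that("the Gini learner matches an established CART on separable data", {
  skip_if_not_installed("rpart")
  rs <- load_ruleset(demo_ruleset_path())
  recs <- generate_patient_states(600, rs, seed = 65)
  states <- lapply(recs, `[[`, "state")
  y <- vapply(recs, `[[`, character(1), "action")
  df <- gericare:::.states_to_frame(states)
  df[] <- lapply(df, function(col) if (is.character(col)) factor(col) else col)
  ref <- rpart::rpart(y ~ ., data = cbind(df, y = factor(y)),
                      method = "class", parms = list(split = "gini"),
                      control = rpart::rpart.control(maxdepth = 3,
                                                     minbucket = 6, cp = 0,
                                                     minsplit = 12,
                                                     xval = 0))
  ref_pred <- as.character(predict(ref, df, type = "class"))
  ours <- fit_tree(recs, max_depth = 3, min_samples = 6)
  our_pred <- predict_care_tree(ours, states)
  # independent learners need not split identically, but on data this
  # separable their training predictions should agree almost everywhere
  expect_gt(mean(our_pred == ref_pred), 0.95)
})

test_that("fitted trees always respect depth and leaf-support bounds", {
  rs <- load_ruleset(demo_ruleset_path())
  for (seed in c(61, 62, 63)) {
    recs <- generate_patient_states(150, rs, seed = seed)
    tree <- fit_tree(recs, max_depth = 3, min_samples = 6)
    expect_lte(gericare:::tree_depth(tree$root), 3)
    expect_true(all(gericare:::tree_leaf_supports(tree$root) >= 6))
  }
  # single-class data -> a valid single-leaf tree
  one <- lapply(1:10, function(i) list(state = base_state(),
                                       action = "monitor"))
  t1 <- fit_tree(one)
  expect_equal(t1$root$type, "leaf")
  expect_equal(predict_care_tree(t1, list(base_state())), "monitor")
})

test_that("care trees serialize to JSON and predict identically", {
  rs <- load_ruleset(demo_ruleset_path())
  recs <- generate_patient_states(300, rs, seed = 70)
  tree <- fit_tree(recs)
  path <- tempfile(fileext = ".json")
  write_tree_json(tree, path)
  back <- read_tree_json(path, class = c("care_tree", "gini_tree"))
  probe <- lapply(generate_patient_states(100, rs, seed = 71), `[[`, "state")
  expect_identical(predict_care_tree(tree, probe),
                   predict_care_tree(back, probe))
  unlink(path)
})

test_that("recommend returns a replayable trace from either recommender", {
  rs <- load_ruleset(demo_ruleset_path())
  st <- base_state(Con = "unconscious")
  rec <- recommend(st, rs)
  expect_equal(rec$action, "extra_situation")
  # replay: the first trace id, evaluated alone, reproduces the action
  first_rule <- Filter(function(r) r$id == rec$trace[1], rs$rules)[[1]]
  replay <- evaluate_rules(st, rule_set(list(first_rule)))
  expect_equal(replay$action, rec$action)

  # untouched state -> default
  expect_equal(recommend(base_state(), rule_set(list()))$action,
               "continue_current_treatment")

  # the tree route agrees on a state it was trained to label
  recs <- generate_patient_states(800, rs, seed = 72)
  tree <- fit_tree(recs)
  st2 <- base_state(MoveH = "falling on the ground")
  expect_equal(recommend(st2, tree)$action, recommend(st2, rs)$action)
  expect_gt(length(recommend(st2, tree)$trace), 0)

  # a habit verdict populates MoveH before evaluation
  v <- classify_movement_change(c(4, 6, 8))
  expect_equal(v$value, "slowed_down")
  rec2 <- recommend(base_state(RiskC = "medium", Diseases = "dementia"),
                    rs, habit_verdict = v)
  expect_equal(rec2$action, "monitor")  # MO05 fires on slowed-down habits
})
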