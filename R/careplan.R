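#' @name careplan
#' @title Care-plan decision support
#' @description
#' Two interchangeable recommenders map a 21-variable patient state to one
#' of four care-plan actions: an IF-THEN rule engine (rules written by care
#' staff, severity-first evaluation, `continue_current_treatment` default)
#' and a Gini-impurity decision tree (depth <= 3, at least 6 records per
#' leaf) trained to emulate the rules.
NULL

.rule_ops <- c("eq", "in", "ge", "le")

#' Construct and validate a rule set
#'
#' Each rule is a conjunction of `(variable, operator, value)` conditions
#' over patient-state fields plus an action and an integer priority.
#' Validation happens at load time: a rule referencing an unknown variable
#' or a value outside the variable's value set is rejected here, never at
#' evaluation. Evaluation order is severity of action (descending), then
#' priority (descending), then id (ascending).
#'
#' @param rules List of rules, each `list(id, conditions = list(list(
#'   variable, op, value), ...), action, priority)`.
#' @param default_action Action when no rule matches.
#' @return An object of class `rule_set` with rules pre-sorted in
#'   evaluation order.
#' @export
rule_set <- function(rules, default_action = "continue_current_treatment") {
  schema <- patient_state_schema()
  default_action <- match.arg(default_action, plan_actions())
  ids <- vapply(rules, function(r) as.character(r$id), character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate rule id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  for (r in rules) {
    if (!r$action %in% plan_actions()) {
      stop("rule ", r$id, ": unknown action '", r$action, "'")
    }
    for (cond in r$conditions) {
      if (!cond$op %in% .rule_ops) {
        stop("rule ", r$id, ": unknown operator '", cond$op, "'")
      }
      if (cond$variable == "height") {
        if (!cond$op %in% c("ge", "le")) {
          stop("rule ", r$id, ": height supports only ge/le")
        }
        next
      }
      if (!cond$variable %in% names(schema)) {
        stop("rule ", r$id, ": unknown variable '", cond$variable, "'")
      }
      vals <- unlist(cond$value)
      if (cond$op %in% c("eq", "in")) {
        bad <- setdiff(vals, schema[[cond$variable]])
        if (length(bad) > 0) {
          stop("rule ", r$id, ": value(s) not in ", cond$variable,
               " value set: ", paste(bad, collapse = ", "))
        }
      } else {
        stop("rule ", r$id, ": ge/le only apply to numeric fields (height)")
      }
    }
  }
  sev <- plan_action_severity()
  actions <- vapply(rules, function(r) r$action, character(1))
  prio <- vapply(rules, function(r) as.numeric(r$priority %||% 0), numeric(1))
  ord <- order(-sev[actions], -prio, ids, method = "radix")
  structure(list(rules = rules[ord], default_action = default_action),
            class = "rule_set")
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("<rule_set> %d rules, default = %s\n",
              length(x$rules), x$default_action))
  invisible(x)
}

#' Load a rule set from YAML
#'
#' Expected layout: a list of `{id, if: [{var, op, value}], then, priority}`
#' entries under a top-level `rules` key (or at the top level).
#'
#' @param path YAML file path.
#' @return A [rule_set()].
#' @export
load_ruleset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- yaml::read_yaml(path)
  entries <- doc$rules %||% doc
  rules <- lapply(entries, function(e) {
    list(id = e$id,
         conditions = lapply(e$`if`, function(cnd) {
           list(variable = cnd$var, op = cnd$op, value = cnd$value)
         }),
         action = e$then,
         priority = e$priority %||% 0)
  })
  rule_set(rules, default_action = doc$default %||% "continue_current_treatment")
}

.condition_holds <- function(cond, state) {
  v <- state[[cond$variable]]
  if (is.null(v) || all(is.na(v))) return(FALSE)
  switch(cond$op,
         eq = as.character(v) == as.character(cond$value),
         `in` = as.character(v) %in% unlist(cond$value),
         ge = as.numeric(v) >= as.numeric(cond$value),
         le = as.numeric(v) <= as.numeric(cond$value))
}

.rule_matches <- function(rule, state) {
  all(vapply(rule$conditions, .condition_holds, logical(1), state = state))
}

#' Evaluate a patient state against a rule set
#'
#' Returns the action of the first rule matched in evaluation order
#' (severity desc, priority desc, id asc), or the default action with an
#' empty match list when nothing fires. Pure and deterministic.
#'
#' @param state A [patient_state()].
#' @param ruleset A [rule_set()].
#' @return List with `action` and `matched_ids` (ids of all matching
#'   rules, in evaluation order; the first decided the action).
#' @export
evaluate_rules <- function(state, ruleset) {
  stopifnot(inherits(ruleset, "rule_set"))
  validate_patient_state(state)
  hits <- vapply(ruleset$rules, .rule_matches, logical(1), state = state)
  ids <- vapply(ruleset$rules, function(r) as.character(r$id), character(1))
  if (!any(hits)) {
    return(list(action = ruleset$default_action, matched_ids = character(0)))
  }
  first <- which(hits)[1]
  list(action = ruleset$rules[[first]]$action, matched_ids = ids[hits])
}

# patient states -> model frame for the tree learner: 21 categoricals as
# character columns plus height as numeric
.states_to_frame <- function(states) {
  schema <- patient_state_schema()
  cols <- lapply(names(schema), function(v) {
    vapply(states, function(s) as.character(s[[v]]), character(1))
  })
  names(cols) <- names(schema)
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  df$height <- vapply(states, function(s) as.numeric(s[["height"]]), numeric(1))
  df
}

#' Fit the care-plan decision tree
#'
#' Greedy binary splits maximizing Gini decrease, with pre-pruning against
#' overfitting: depth capped at `max_depth` and at least `min_samples`
#' training records in every leaf. Categorical variables split as one-hot
#' equality tests, which keeps a depth-3 tree interpretable. Leaf ties are
#' broken toward the more severe action so emergencies are never lost.
#'
#' @param records List of `list(state, action)` pairs (e.g. from
#'   [generate_patient_states()]).
#' @param max_depth Maximum tree depth (default 3).
#' @param min_samples Minimum records per leaf (default 6).
#' @param seed Unused by the deterministic learner; accepted so callers can
#'   treat all model fits uniformly.
#' @return An object of class `care_tree`.
#' @export
fit_tree <- function(records, max_depth = 3, min_samples = 6, seed = NULL) {
  states <- lapply(records, `[[`, "state")
  actions <- vapply(records, function(r) as.character(r$action), character(1))
  if (length(unique(actions)) < 2) {
    # degenerate but valid: a single all-one-class leaf
    counts <- table(actions)
    tree <- structure(list(
      root = list(type = "leaf", action = names(counts)[1],
                  counts = as.list(as.integer(counts)),
                  classes = names(counts)),
      classes = names(counts), max_depth = max_depth,
      min_samples = min_samples), class = "gini_tree")
  } else {
    x <- .states_to_frame(states)
    tree <- fit_decision_tree(x, actions, max_depth = max_depth,
                              min_samples = min_samples,
                              class_priority = plan_action_severity())
  }
  class(tree) <- c("care_tree", "gini_tree")
  tree
}

#' Predict care-plan actions with a fitted tree
#'
#' @param object A `care_tree`.
#' @param states List of [patient_state()] objects.
#' @param ... Unused.
#' @return Character vector of plan actions.
#' @export
predict_care_tree <- function(object, states, ...) {
  stopifnot(inherits(object, "care_tree"))
  predict_decision_tree(object, .states_to_frame(states))
}

#' Recommend a care-plan action with an explanation trace
#'
#' Evaluates exactly one recommender — a rule set or a fitted care tree —
#' and reports the action together with how it was reached: the matched
#' rule ids, or the root-to-leaf path of tests. When a movement-habit
#' verdict is supplied, the state's `MoveH` field is populated from it
#' before evaluation.
#'
#' @param state A [patient_state()].
#' @param recommender A [rule_set()] or `care_tree`.
#' @param habit_verdict Optional [classify_movement_change()] result used
#'   to auto-populate `MoveH`.
#' @return List of class `care_recommendation` with `action`, `trace` and
#'   `recommender` (`"rules"` or `"tree"`).
#' @export
recommend <- function(state, recommender, habit_verdict = NULL) {
  if (!is.null(habit_verdict)) {
    stopifnot(inherits(habit_verdict, "habit_verdict"))
    state[["MoveH"]] <- gsub("_", " ", habit_verdict$value)
  }
  validate_patient_state(state)
  if (inherits(recommender, "rule_set")) {
    res <- evaluate_rules(state, recommender)
    out <- list(action = res$action, trace = res$matched_ids,
                recommender = "rules")
  } else if (inherits(recommender, "care_tree")) {
    route <- .tree_route(recommender$root,
                         .states_to_frame(list(state))[1, , drop = FALSE])
    out <- list(action = route$action, trace = route$path,
                recommender = "tree")
  } else {
    stop("recommender must be a rule_set or a care_tree")
  }
  structure(out, class = "care_recommendation")
}

#' @export
print.care_recommendation <- function(x, ...) {
  cat(sprintf("<care_recommendation> %s (via %s)\n", x$action, x$recommender))
  if (length(x$trace)) cat("  trace:", paste(x$trace, collapse = " -> "), "\n")
  invisible(x)
}

#' Path to the bundled demonstration rule set
#'
#' An illustrative ~20-rule care-plan rule set in the style staff-authored
#' IF-THEN rules take (the production rule base of a real deployment is
#' private). Covers all four actions.
#'
#' @return File path of the YAML rule set.
#' @export
demo_ruleset_path <- function() {
  system.file("extdata", "demo_ruleset.yaml", package = "gericare",
              mustWork = TRUE)
}
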