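#' ADME screening rule set
#'
#' Bundles the thresholds used to screen formula components for drug-likeness
#' and oral activity. The defaults combine the Lipinski-style rules
#' (MW < 500 Da, H-bond donors <= 5, H-bond acceptors <= 10, rotatable bonds
#' <= 10, -2 < logP < 5) with an oral-bioavailability floor (OB >= 30%) and,
#' when the corresponding columns are present, the categorical predictor
#' rules: GI absorption must be "high", components with "high" hERG
#' inhibition are removed, and carcinogenicity must be "negative".
#'
#' The donor/acceptor bounds are inclusive. A strictly-less-than reading of
#' the donor rule would reject quercetin (5 donors), a component every
#' reference selection retains, so `strict = TRUE` is offered only as an
#' explicit variant.
#'
#' @param mw_max Maximum molecular weight (exclusive), Da.
#' @param hdon_max Maximum H-bond donor count.
#' @param hacc_max Maximum H-bond acceptor count.
#' @param rbn_max Maximum rotatable-bond count.
#' @param logp_min,logp_max Open logP interval.
#' @param ob_min Minimum oral bioavailability (inclusive), percent.
#' @param require_gi Require `gi_class == "high"` when the column carries
#'   information (`TRUE`/`FALSE`).
#' @param exclude_herg Remove components with `herg_class == "high"`.
#' @param require_negative_carcinogenicity Keep only
#'   `carcinogenicity == "negative"` when known.
#' @param unknown Policy for "unknown" categorical values: `"skip"` (the rule
#'   does not fire; default) or `"fail"`.
#' @param strict Use strict `<` for the donor/acceptor/rotatable-bond counts
#'   instead of the inclusive defaults.
#' @return A list of class `adme_rules`.
#' @export
adme_rules <- function(mw_max = 500, hdon_max = 5, hacc_max = 10,
                       rbn_max = 10, logp_min = -2, logp_max = 5,
                       ob_min = 30, require_gi = TRUE, exclude_herg = TRUE,
                       require_negative_carcinogenicity = TRUE,
                       unknown = c("skip", "fail"), strict = FALSE) {
  unknown <- match.arg(unknown)
  stopifnot(is.finite(mw_max), is.finite(hdon_max), is.finite(hacc_max),
            is.finite(rbn_max), is.finite(logp_min), is.finite(logp_max),
            is.finite(ob_min), logp_min < logp_max)
  structure(list(mw_max = mw_max, hdon_max = hdon_max, hacc_max = hacc_max,
                 rbn_max = rbn_max, logp_min = logp_min, logp_max = logp_max,
                 ob_min = ob_min, require_gi = isTRUE(require_gi),
                 exclude_herg = isTRUE(exclude_herg),
                 require_negative_carcinogenicity =
                   isTRUE(require_negative_carcinogenicity),
                 unknown = unknown, strict = isTRUE(strict)),
            class = "adme_rules")
}

#' Evaluate one component against a rule set
#'
#' @param record A one-row `component_table` data frame (or a list with the
#'   same fields).
#' @param rules An [adme_rules()] object.
#' @return A list of class `screen_verdict` with `component_id`, a named
#'   logical vector `rules` (one entry per enabled rule), and `pass` — the
#'   conjunction of all enabled rules.
#' @export
evaluate_component <- function(record, rules = adme_rules()) {
  stopifnot(inherits(rules, "adme_rules"))
  cmp_count <- if (rules$strict) `<` else `<=`
  verdicts <- c(
    mw   = record$mw < rules$mw_max,
    hdon = cmp_count(record$hdon, rules$hdon_max),
    hacc = cmp_count(record$hacc, rules$hacc_max),
    rbn  = cmp_count(record$rbn, rules$rbn_max),
    logp = record$logp > rules$logp_min & record$logp < rules$logp_max,
    ob   = record$ob >= rules$ob_min
  )
  cat_rule <- function(value, wanted, exclude = FALSE) {
    if (is.null(value) || is.na(value) || identical(value, "unknown")) {
      return(if (rules$unknown == "fail") FALSE else NA)
    }
    if (exclude) value != wanted else value == wanted
  }
  if (rules$require_gi) {
    verdicts["gi"] <- cat_rule(record$gi_class, "high")
  }
  if (rules$exclude_herg) {
    verdicts["herg"] <- cat_rule(record$herg_class, "high", exclude = TRUE)
  }
  if (rules$require_negative_carcinogenicity) {
    verdicts["carcinogenicity"] <- cat_rule(record$carcinogenicity, "negative")
  }
  # NA = rule skipped for an unknown value; it never decides the verdict
  structure(list(component_id = record$id, rules = verdicts,
                 pass = all(verdicts, na.rm = TRUE)),
            class = "screen_verdict")
}

#' Screen a component table
#'
#' Applies [evaluate_component()] to every row and splits the table into kept
#' and rejected components. The verdict table is a partition of the input:
#' every component appears exactly once, in input order.
#'
#' @param components A `component_table` (see [read_component_table()]).
#' @param rules An [adme_rules()] object.
#' @return A list of class `screen_result`: `kept` (subset of `components`,
#'   input order preserved), `verdicts` (data frame with one logical column
#'   per rule plus `pass`), and `rules`.
#' @export
screen_components <- function(components, rules = adme_rules()) {
  if (nrow(components) == 0L) {
    warning("screening an empty component table", call. = FALSE)
  }
  verdict_list <- lapply(seq_len(nrow(components)), function(i) {
    evaluate_component(components[i, , drop = FALSE], rules)
  })
  rule_names <- if (length(verdict_list) > 0L) {
    names(verdict_list[[1]]$rules)
  } else {
    character(0)
  }
  verdicts <- data.frame(id = components$id, stringsAsFactors = FALSE)
  for (rn in rule_names) {
    verdicts[[rn]] <- vapply(verdict_list, function(v) v$rules[[rn]], logical(1))
  }
  verdicts$pass <- vapply(verdict_list, `[[`, logical(1), "pass")
  kept <- components[verdicts$pass %in% TRUE, , drop = FALSE]
  structure(list(kept = kept, verdicts = verdicts, rules = rules),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  n <- nrow(x$verdicts)
  cat(sprintf("ADME screen: %d / %d components kept\n", nrow(x$kept), n))
  rule_cols <- setdiff(names(x$verdicts), c("id", "pass"))
  for (rn in rule_cols) {
    fails <- sum(!x$verdicts[[rn]], na.rm = TRUE)
    skipped <- sum(is.na(x$verdicts[[rn]]))
    cat(sprintf("  %-16s %4d fail%s\n", rn, fails,
                if (skipped > 0) sprintf(" (%d unknown, skipped)", skipped) else ""))
  }
  invisible(x)
}

#' @export
print.screen_verdict <- function(x, ...) {
  cat(sprintf("component %s: %s\n", x$component_id,
              if (x$pass) "PASS" else "FAIL"))
  shown <- ifelse(is.na(x$rules), "skip", ifelse(x$rules, "ok", "FAIL"))
  cat(paste(sprintf("  %s=%s", names(x$rules), shown), collapse = "\n"), "\n")
  invisible(x)
}
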