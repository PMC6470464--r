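# Treatment-cascade key performance indicators. Every value is a ratio of
# exact integer counts (no floating accumulation); ratios are expressed as
# percentages, and a ratio with a zero denominator is undefined (NA with a
# reason), never 0 or 100 — small cells must not fabricate extreme
# performance.

#' Define an indicator
#'
#' An indicator is either a `number` (a count of participants matching the
#' numerator predicate) or a `ratio` (percentage of the denominator
#' population matching the numerator predicate).
#'
#' @param name short machine name.
#' @param kind `"number"` or `"ratio"`.
#' @param numerator predicate: function of the participants data.frame
#'   returning a logical vector.
#' @param denominator predicate for the base population; required for
#'   ratios, ignored for numbers.
#' @param description display text.
#' @param info_text method note shown on demand (how the indicator is
#'   calculated).
#' @param target optional target percentage displayed alongside the value.
#' @return object of class `indicator_definition`.
#' @export
indicator_definition <- function(name, kind = c("ratio", "number"),
                                 numerator, denominator = NULL,
                                 description = name, info_text = "",
                                 target = NULL) {
  kind <- match.arg(kind)
  if (kind == "ratio" && is.null(denominator)) {
    stop("ratio indicator '", name, "' needs a denominator predicate")
  }
  structure(list(name = name, kind = kind, numerator = numerator,
                 denominator = denominator, description = description,
                 info_text = info_text, target = target),
            class = "indicator_definition")
}

indicator_numerator <- function(defn, participants) {
  as.logical(defn$numerator(participants))
}

indicator_denominator <- function(defn, participants) {
  if (defn$kind == "number" || is.null(defn$denominator)) {
    rep(TRUE, nrow(participants))
  } else {
    as.logical(defn$denominator(participants))
  }
}

#' Built-in treatment-cascade indicator catalog
#'
#' The five shipped indicators, in cascade order: trial participant count,
#' HIV prevalence, and the three nested cascade ratios aligned with the
#' UNAIDS 90/90/90 targets (diagnosed among positive, on ART among
#' diagnosed, virally suppressed among on ART). Each cascade ratio's
#' denominator predicate equals the previous ratio's numerator predicate,
#' so cascade linkage holds by construction.
#'
#' @param targets named numeric vector of per-indicator target percentages;
#'   defaults to 90 for the three cascade ratios.
#' @return named list of [indicator_definition()]s in cascade order.
#' @export
cascade_indicators <- function(targets = c(diagnosed_of_positive = 90,
                                           art_of_diagnosed = 90,
                                           suppressed_of_art = 90)) {
  tgt <- function(nm) if (nm %in% names(targets)) unname(targets[nm]) else NULL
  defs <- list(
    indicator_definition(
      "trial_participants", "number",
      numerator = function(p) rep(TRUE, nrow(p)),
      description = "Trial participants",
      info_text = "The number of individuals enrolled in the trial."
    ),
    indicator_definition(
      "hiv_prevalence", "ratio",
      numerator = function(p) p$hiv_positive,
      denominator = function(p) rep(TRUE, nrow(p)),
      description = "HIV prevalence rate",
      info_text = "The percentage of individuals known to be HIV positive.",
      target = tgt("hiv_prevalence")
    ),
    indicator_definition(
      "diagnosed_of_positive", "ratio",
      numerator = function(p) p$knows_status,
      denominator = function(p) p$hiv_positive,
      description = "HIV-positive individuals who know their status",
      info_text = paste("The percentage of HIV-positive individuals who know",
                        "their status, of the individuals known to be positive."),
      target = tgt("diagnosed_of_positive")
    ),
    indicator_definition(
      "art_of_diagnosed", "ratio",
      numerator = function(p) p$on_art,
      denominator = function(p) p$knows_status,
      description = "HIV-positive individuals on antiretroviral treatment (ART)",
      info_text = paste("The percentage of diagnosed HIV-positive individuals",
                        "on antiretroviral treatment."),
      target = tgt("art_of_diagnosed")
    ),
    indicator_definition(
      "suppressed_of_art", "ratio",
      numerator = function(p) p$virally_suppressed,
      denominator = function(p) p$on_art,
      description = "Individuals who are virally suppressed",
      info_text = paste("The percentage of individuals on ART who are",
                        "virally suppressed."),
      target = tgt("suppressed_of_art")
    )
  )
  stats::setNames(defs, vapply(defs, function(d) d$name, character(1)))
}

#' Parse a custom indicator declared in a dashboard config
#'
#' Custom indicators declare numerator/denominator as simple field-comparison
#' expressions over participant columns, e.g. `"on_art & sex == 'female'"`.
#' Only participant fields, literals, comparison and boolean operators are
#' allowed.
#'
#' @param name indicator name.
#' @param spec list with `kind`, `numerator`, optional `denominator`,
#'   `description`, `info_text`, `target`.
#' @return an [indicator_definition()].
#' @export
custom_indicator <- function(name, spec) {
  mk <- function(expr_str) {
    ex <- str2lang(expr_str)
    ok <- c(participant_columns, "TRUE", "FALSE", "T", "F")
    bad <- setdiff(all.vars(ex), ok)
    if (length(bad) > 0) {
      stop("custom indicator '", name, "' references unknown field(s): ",
           paste(bad, collapse = ", "))
    }
    allowed_fun <- c("==", "!=", "<", "<=", ">", ">=", "&", "|", "!", "(",
                     "%in%", "c")
    bad_fun <- setdiff(setdiff(all.names(ex), all.vars(ex)), allowed_fun)
    if (length(bad_fun) > 0) {
      stop("custom indicator '", name, "' uses disallowed function(s): ",
           paste(bad_fun, collapse = ", "))
    }
    function(p) eval(ex, envir = p, enclos = baseenv())
  }
  indicator_definition(
    name,
    kind = if (is.null(spec$kind)) "ratio" else spec$kind,
    numerator = mk(spec$numerator),
    denominator = if (!is.null(spec$denominator)) mk(spec$denominator),
    description = if (is.null(spec$description)) name else spec$description,
    info_text = if (is.null(spec$info_text)) "" else spec$info_text,
    target = spec$target
  )
}

#' Evaluate one indicator over a set of participants
#'
#' @param defn an [indicator_definition()].
#' @param participants data.frame of participant records.
#' @param scope `"global"` or a cell key as `c(q, r)`.
#' @return object of class `indicator_value`: `indicator`, `scope`,
#'   `numerator`, `denominator` (NA for numbers), `value` (count for
#'   numbers, percentage for ratios, NA when the denominator is zero),
#'   `undefined_reason` (NULL unless undefined), `target`.
#' @export
compute_indicator <- function(defn, participants, scope = "global") {
  stopifnot(inherits(defn, "indicator_definition"))
  num_mask <- indicator_numerator(defn, participants)
  num <- sum(num_mask)
  if (defn$kind == "number") {
    return(structure(list(indicator = defn$name, scope = scope,
                          numerator = num, denominator = NA_integer_,
                          value = num, undefined_reason = NULL,
                          target = defn$target),
                     class = "indicator_value"))
  }
  den <- sum(indicator_denominator(defn, participants))
  value <- if (den > 0) 100 * num / den else NA_real_
  structure(list(indicator = defn$name, scope = scope,
                 numerator = num, denominator = den, value = value,
                 undefined_reason = if (den == 0) "denominator is zero",
                 target = defn$target),
            class = "indicator_value")
}

#' Evaluate the full cascade over a set of participants
#'
#' @param spec list of [indicator_definition()]s in cascade order (see
#'   [cascade_indicators()]).
#' @param participants data.frame of participant records (for cell scope,
#'   the cell's assignees).
#' @param scope `"global"` or a cell key `c(q, r)`.
#' @return list of [compute_indicator()] values, one per spec entry, in
#'   order.
#' @export
compute_cascade <- function(spec, participants, scope = "global") {
  lapply(spec, compute_indicator, participants = participants, scope = scope)
}

#' Pair local and global indicator values
#'
#' @param spec the cascade spec both value lists were computed from.
#' @param cell_values list of [compute_indicator()] values at cell scope.
#' @param global_values list at global scope.
#' @return data.frame with one row per indicator: `indicator`, `local`,
#'   `global`, `difference` (percentage points, NA when local undefined),
#'   `target`.
#' @export
compare_local_global <- function(spec, cell_values, global_values) {
  nm_l <- vapply(cell_values, function(v) v$indicator, character(1))
  nm_g <- vapply(global_values, function(v) v$indicator, character(1))
  nm_s <- vapply(spec, function(d) d$name, character(1))
  if (!identical(nm_l, nm_s) || !identical(nm_g, nm_s)) {
    stop("contract error: indicator lists do not match the cascade spec")
  }
  local <- vapply(cell_values, function(v) as.numeric(v$value), numeric(1))
  global <- vapply(global_values, function(v) as.numeric(v$value), numeric(1))
  target <- vapply(spec, function(d) {
    if (is.null(d$target)) NA_real_ else d$target
  }, numeric(1))
  data.frame(indicator = nm_s, local = local, global = global,
             difference = local - global, target = target,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Categorical breakdown with the two normalization modes
#'
#' Tallies a categorical participant field either over the whole base
#' population (`total_population`) or restricted to the participants
#' matching an indicator's numerator predicate (`indicator_population`,
#' e.g. HIV-positive individuals only). Proportions sum to 1 when the base
#' is nonempty; an empty base is flagged as undefined rather than producing
#' NaN.
#'
#' @param participants data.frame of participant records.
#' @param variable one of the categorical fields (`sex`, `education`,
#'   `relationship_status`, `employment`).
#' @param mode `"total_population"` or `"indicator_population"`.
#' @param indicator the [indicator_definition()] whose numerator set defines
#'   the base in `indicator_population` mode.
#' @return list: `variable`, `mode`, `base_size`, `counts` (named integer),
#'   `proportions` (named numeric), `undefined` (TRUE when base empty).
#' @export
normalize_breakdown <- function(participants, variable,
                                mode = c("total_population",
                                         "indicator_population"),
                                indicator = NULL) {
  mode <- match.arg(mode)
  if (!variable %in% c("sex", .cat_cols)) {
    stop("'", variable, "' is not a categorical participant field")
  }
  base <- participants
  if (mode == "indicator_population") {
    if (is.null(indicator)) {
      stop("indicator_population mode needs an indicator")
    }
    base <- participants[indicator_numerator(indicator, participants), ,
                         drop = FALSE]
  }
  counts <- table(base[[variable]])
  counts <- stats::setNames(as.integer(counts), names(counts))
  n <- sum(counts)
  list(variable = variable, mode = mode, base_size = n, counts = counts,
       proportions = if (n > 0) counts / n else stats::setNames(numeric(0),
                                                                character(0)),
       undefined = n == 0)
}
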