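## Substituent-effect modelling: relate the catalytic field delta_s at
## substitution-site probes to observed (QM-computed) activation-barrier
## changes by ordinary least squares, predict unmeasured sites, rank sites
## for screening, and flag sites too close to the reacting region for the
## point-potential picture to hold.

#' Assemble substitution records
#'
#' One record per candidate H→substituent site, pairing the catalytic field
#' at the site's probe with the observed barrier change (when available).
#'
#' @param site_label Character site labels.
#' @param site_index 1-based H atom indices (may be `NA`).
#' @param delta_s Catalytic field at the site probe, kcal mol^-1 e^-1.
#' @param observed_delta Optional observed barrier change on substitution,
#'   kcal mol^-1 (`NA` when not measured).
#' @return Data frame with columns `site_label`, `site_index`, `delta_s`,
#'   `observed_delta`, `predicted_delta` (NA), `near_reaction` (FALSE).
#' @export
substitution_records <- function(site_label, site_index = NA_integer_,
                                 delta_s, observed_delta = NA_real_) {
  df <- data.frame(site_label = as.character(site_label),
                   site_index = as.integer(site_index),
                   delta_s = as.numeric(delta_s),
                   observed_delta = as.numeric(observed_delta),
                   predicted_delta = NA_real_,
                   near_reaction = FALSE,
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$delta_s))) stop("delta_s must be finite")
  if (any(!is.na(df$observed_delta) & !is.finite(df$observed_delta)))
    stop("observed_delta must be finite when present")
  df
}

#' Fit the linear catalytic-field model
#'
#' Ordinary least squares of the observed barrier change on the catalytic
#' field at the substitution-site probes:
#' `observed_delta ~ slope * delta_s (+ intercept)`. Sites flagged
#' `near_reaction` (see [flag_near_reaction_sites()]) and sites named in
#' `exclude` are left out of the fit (but can still be predicted).
#'
#' @param records Substitution-record data frame (see
#'   [substitution_records()]); rows with `NA` observed_delta are ignored.
#' @param use_intercept Include an intercept (default `TRUE`; an intercept
#'   absorbs systematic non-electrostatic offsets).
#' @param exclude Character vector of `site_label`s to exclude from fitting.
#' @param drop_near_reaction Exclude rows flagged `near_reaction`
#'   (default `TRUE`).
#' @return Object of class `field_model`: `slope` (e), `intercept`
#'   (kcal mol^-1; 0 when `use_intercept = FALSE`), `residual_sd`
#'   (kcal mol^-1, `sqrt(SSR / (n - p))`), `n_used`, `excluded_labels`,
#'   `use_intercept`, and the underlying `fit` (an `lm`).
#' @export
fit_field_model <- function(records, use_intercept = TRUE,
                            exclude = character(0),
                            drop_near_reaction = TRUE) {
  stopifnot(is.data.frame(records),
            all(c("site_label", "delta_s", "observed_delta") %in% names(records)))
  excluded <- as.character(exclude)
  keep <- !is.na(records$observed_delta) &
    !(records$site_label %in% excluded)
  if (drop_near_reaction && "near_reaction" %in% names(records))
    keep <- keep & !records$near_reaction
  d <- records[keep, , drop = FALSE]
  p <- if (use_intercept) 2L else 1L
  if (nrow(d) < max(p, 2L))
    stop(sprintf("need at least %d records with observed_delta after exclusions, got %d",
                 max(p, 2L), nrow(d)))
  if (max(d$delta_s) - min(d$delta_s) < 1e-12)
    stop("degenerate design: delta_s has zero variance across fitted records")
  fit <- if (use_intercept)
    stats::lm(observed_delta ~ delta_s, data = d)
  else
    stats::lm(observed_delta ~ delta_s - 1, data = d)
  cf <- stats::coef(fit)
  slope <- unname(cf[["delta_s"]])
  intercept <- if (use_intercept) unname(cf[["(Intercept)"]]) else 0
  dfres <- nrow(d) - p
  if (dfres == 0L) {
    warning("saturated fit: zero residual degrees of freedom; residual_sd reported as 0")
    rsd <- 0
  } else {
    rsd <- sqrt(sum(stats::residuals(fit)^2) / dfres)
  }
  structure(list(slope = slope, intercept = intercept, residual_sd = rsd,
                 n_used = nrow(d), excluded_labels = excluded,
                 use_intercept = use_intercept, fit = fit),
            class = "field_model")
}

#' @export
print.field_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<field_model> delta = %.4f * delta_s %s %.4f\n",
    "  residual SD %.4f kcal mol^-1 on %d sites (%d excluded by label)\n"),
    x$slope, if (x$intercept < 0) "-" else "+", abs(x$intercept),
    x$residual_sd, x$n_used, length(x$excluded_labels)))
  invisible(x)
}

#' Predict barrier changes from the fitted field model
#'
#' Fills `predicted_delta = slope * delta_s + intercept` for every record
#' (including excluded and near-reaction sites); other columns untouched.
#'
#' @param model A [fit_field_model()] result.
#' @param records Substitution-record data frame.
#' @return `records` with `predicted_delta` filled.
#' @export
predict_substituent_effects <- function(model, records) {
  stopifnot(inherits(model, "field_model"), is.data.frame(records),
            "delta_s" %in% names(records))
  records$predicted_delta <- model$slope * records$delta_s + model$intercept
  records
}

#' Flag substitution sites in the direct vicinity of the reacting region
#'
#' Sites whose hydrogen lies within `cutoff` of any reacting atom are
#' flagged `near_reaction = TRUE`: there, non-electrostatic effects dominate
#' and the point-potential model is unreliable. Flagged sites are excluded
#' from [fit_field_model()] by default but still receive predictions.
#'
#' @param records Substitution-record data frame with valid `site_index`.
#' @param mol The substrate-frame [molecule()].
#' @param reacting_atoms 1-based indices of the reacting atoms.
#' @param cutoff Distance cutoff in Å (default 3.0).
#' @return `records` with `near_reaction` updated.
#' @export
flag_near_reaction_sites <- function(records, mol, reacting_atoms,
                                     cutoff = 3.0) {
  stopifnot(is.data.frame(records), inherits(mol, "molecule"))
  reacting_atoms <- as.integer(reacting_atoms)
  if (any(reacting_atoms < 1L | reacting_atoms > n_atoms(mol)))
    stop("reacting atom index out of bounds")
  flag <- logical(nrow(records))
  for (r in seq_len(nrow(records))) {
    i <- records$site_index[r]
    if (is.na(i)) next
    dd <- sqrt(rowSums(sweep(mol$xyz[reacting_atoms, , drop = FALSE],
                             2, mol$xyz[i, ])^2))
    flag[r] <- any(dd < cutoff)
  }
  records$near_reaction <- flag
  records
}

#' Rank substitution sites by predicted catalytic benefit
#'
#' For screening: orders bond-directed sites by the barrier change a
#' substituent of the given charge sign would produce at the site probe. The
#' sign logic is derived from the single-charge identity
#' `Delta = -q * delta_s`: a negatively charged substituent (the H→F case,
#' `substituent_charge = -1`) lowers the barrier most where `delta_s` is
#' most negative; a positive one where `delta_s` is most positive.
#'
#' @param values Catalytic-field data frame from
#'   [compute_catalytic_field()]; all rows must be `kind = "bond_directed"`.
#' @param objective `"lower"` (rank by barrier lowering, best first) or
#'   `"raise"` (the exact reverse).
#' @param substituent_charge Sign/magnitude of the effective substituent
#'   charge at the probe, e (default -1, electronegative substituent).
#' @return Character vector of `site_label`s, best first; ties broken by
#'   ascending `site_index`.
#' @export
rank_sites <- function(values, objective = c("lower", "raise"),
                       substituent_charge = -1) {
  objective <- match.arg(objective)
  stopifnot(is.data.frame(values),
            all(c("site_label", "delta_s", "kind") %in% names(values)))
  if (any(values$kind != "bond_directed"))
    stop("rank_sites requires bond-directed probe values only")
  pred <- -substituent_charge * values$delta_s   # Delta for this substituent
  key <- if (objective == "lower") pred else -pred
  idx <- if ("site_index" %in% names(values)) values$site_index
         else seq_len(nrow(values))
  values$site_label[order(key, idx)]
}

#' Serialize a fitted field model to JSON
#'
#' @param model A [fit_field_model()] result.
#' @param path Output path.
#' @export
write_field_model <- function(model, path) {
  stopifnot(inherits(model, "field_model"))
  jsonlite::write_json(
    list(slope = model$slope, intercept = model$intercept,
         residual_sd = model$residual_sd, n_used = model$n_used,
         excluded_labels = as.list(model$excluded_labels),
         use_intercept = model$use_intercept),
    path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Read a serialized field model
#'
#' @param path Path to a JSON file written by [write_field_model()].
#' @return A `field_model` (without the underlying `lm` object).
#' @export
read_field_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(slope = as.numeric(x$slope),
                 intercept = as.numeric(x$intercept),
                 residual_sd = as.numeric(x$residual_sd),
                 n_used = as.integer(x$n_used),
                 excluded_labels = as.character(unlist(x$excluded_labels)),
                 use_intercept = isTRUE(x$use_intercept), fit = NULL),
            class = "field_model")
}
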