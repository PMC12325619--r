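# Simplified analytical-greenness scorers: the 12-principle AGREE weighted
# mean and the 15-criterion / 5-domain GAPI colour profile. These reproduce
# the *structure* of the published assessments; the principle-level inputs
# behind any published score are method-specific and must be supplied by the
# user.

#' AGREE profile: twelve principle scores
#'
#' @param scores Numeric vector of exactly 12 scores, each in \[0, 1\]
#'   (0 = non-green, 1 = fully green).
#' @param weights 12 positive weights (default all 1; the official tool
#'   allows per-principle weighting).
#' @return An `agree_profile` object.
#' @export
agree_profile <- function(scores, weights = rep(1, 12)) {
  if (length(scores) != 12)
    stop("an AGREE profile has exactly 12 principle scores", call. = FALSE)
  if (any(is.na(scores)) || any(scores < 0 | scores > 1))
    stop("principle scores must lie in [0, 1]", call. = FALSE)
  if (length(weights) != 12 || any(!(weights > 0)))
    stop("weights must be 12 positive values", call. = FALSE)
  structure(list(scores = as.numeric(scores),
                 weights = as.numeric(weights)),
            class = "agree_profile")
}

#' AGREE score
#'
#' Weighted mean of the twelve principle scores; full precision is returned
#' (round to 2 decimals for display, as the pictogram does).
#'
#' @param profile An [agree_profile()].
#' @return Score in \[0, 1\].
#' @export
agree_score <- function(profile) {
  if (!inherits(profile, "agree_profile"))
    stop("profile must be an agree_profile", call. = FALSE)
  weighted.mean(profile$scores, profile$weights)
}

#' Default GAPI domain layout
#'
#' Fifteen criteria across the five domains of the assessment: sample
#' handling (4), reagents and solvents (3), instrumentation (3), waste (2),
#' occupational safety (3).
#' @return Named integer vector of domain sizes summing to 15.
#' @export
gapi_domains <- function() {
  c(sample_handling = 4L, reagents_solvents = 3L, instrumentation = 3L,
    waste = 2L, safety = 3L)
}

#' GAPI profile: fifteen colour-coded criteria
#'
#' @param labels Character vector of exactly 15 labels from
#'   `c("green", "yellow", "red")` (green = low environmental impact,
#'   yellow = moderate burden, red = high or undesirable effect), in domain
#'   order.
#' @param domains Named integer vector of domain sizes summing to 15
#'   (default [gapi_domains()]).
#' @return A `gapi_profile` object.
#' @export
gapi_profile <- function(labels, domains = gapi_domains()) {
  if (sum(domains) != 15)
    stop("domain sizes must sum to 15", call. = FALSE)
  if (length(labels) != 15)
    stop("a GAPI profile has exactly 15 criteria", call. = FALSE)
  bad <- setdiff(unique(labels), c("green", "yellow", "red"))
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(labels = labels, domains = domains),
            class = "gapi_profile")
}

#' GAPI summary: colour counts and per-domain breakdown
#'
#' @param profile A [gapi_profile()].
#' @return List: `counts` (named green/yellow/red totals, summing to 15),
#'   `by_domain` (data frame of per-domain colour counts), and `table`
#'   (pictogram-ready data frame of domain, criterion index, label).
#' @export
gapi_summary <- function(profile) {
  if (!inherits(profile, "gapi_profile"))
    stop("profile must be a gapi_profile", call. = FALSE)
  lv <- c("green", "yellow", "red")
  counts <- vapply(lv, function(l) sum(profile$labels == l), integer(1))
  domain <- rep(names(profile$domains), profile$domains)
  by_domain <- do.call(rbind, lapply(unique(domain), function(dm) {
    sub <- profile$labels[domain == dm]
    data.frame(domain = dm,
               green = sum(sub == "green"),
               yellow = sum(sub == "yellow"),
               red = sum(sub == "red"))
  }))
  list(counts = counts, by_domain = by_domain,
       table = data.frame(domain = domain,
                          criterion = seq_along(profile$labels),
                          label = profile$labels))
}

#' Illustrative AGREE/GAPI profiles
#'
#' Demonstration inputs for a solvent-lean direct UV method ("proposed") and
#' a more resource-intensive comparator ("reported"). They exercise the
#' scoring mechanics only; the principle-level inputs behind any published
#' score are not recoverable from final scores and these do not reproduce
#' them.
#'
#' @return List with `agree` (two [agree_profile()]s) and `gapi`
#'   (two [gapi_profile()]s), each named `proposed` / `reported`.
#' @export
example_greenness_profiles <- function() {
  list(
    agree = list(
      proposed = agree_profile(
        c(0.9, 0.8, 1.0, 0.8, 0.6, 0.9, 0.9, 0.7, 0.8, 0.6, 1.0, 0.8)),
      reported = agree_profile(
        c(0.7, 0.6, 0.8, 0.6, 0.5, 0.7, 0.8, 0.6, 0.6, 0.5, 0.9, 0.6))),
    gapi = list(
      proposed = gapi_profile(c(
        "green", "green", "yellow", "green",
        "green", "yellow", "green",
        "green", "green", "yellow",
        "yellow", "green",
        "green", "green", "yellow")),
      reported = gapi_profile(c(
        "yellow", "green", "yellow", "yellow",
        "red", "yellow", "yellow",
        "green", "yellow", "red",
        "red", "yellow",
        "yellow", "yellow", "red"))))
}
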