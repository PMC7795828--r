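#' Piecewise-linear membership function
#'
#' Membership functions are point lists `(x, mu)` with strictly increasing `x`
#' and `mu` in `[0, 1]`; evaluation interpolates linearly between bracketing
#' points and is 0 outside the point list. Triangles and trapezoids are the
#' common special cases.
#'
#' @param x Numeric vector of breakpoints, strictly increasing.
#' @param mu Membership degrees at the breakpoints, each in `[0, 1]`.
#' @return Object of class `membership_function`.
#' @seealso [mf_triangle()], [mf_trapezoid()]
#' @export
membership_function <- function(x, mu) {
  stopifnot(length(x) == length(mu), length(x) >= 2,
            all(diff(x) > 0), all(mu >= 0), all(mu <= 1))
  structure(list(x = as.numeric(x), mu = as.numeric(mu)),
            class = "membership_function")
}

#' @rdname membership_function
#' @param a,b,c,d Breakpoints: triangle feet `a`, `c` with apex `b`; trapezoid
#'   feet `a`, `d` with plateau `[b, c]`. Coincident breakpoints (a shoulder
#'   flush with the range edge) are allowed.
#' @export
mf_triangle <- function(a, b, c) {
  .mf_from_points(c(a, b, c), c(0, 1, 0))
}

#' @rdname membership_function
#' @export
mf_trapezoid <- function(a, b, c, d) {
  .mf_from_points(c(a, b, c, d), c(0, 1, 1, 0))
}

# collapse coincident breakpoints (shoulders flush with the range edge),
# keeping the larger membership
.mf_from_points <- function(x, mu) {
  mx <- tapply(mu, x, max)
  xs <- as.numeric(names(mx))
  o <- order(xs)
  membership_function(xs[o], as.numeric(mx)[o])
}

#' Evaluate a membership function
#'
#' @param mf A [membership_function()].
#' @param x Numeric vector of points.
#' @return Membership degrees in `[0, 1]`; 0 outside the point list's support.
#' @export
membership <- function(mf, x) {
  stopifnot(inherits(mf, "membership_function"))
  out <- stats::approx(mf$x, mf$mu, xout = x, rule = 1, ties = "ordered")$y
  out[is.na(out)] <- 0
  out
}

#' Fuzzy linguistic variable
#'
#' @param name Variable name.
#' @param range Numeric `c(min, max)` universe of discourse.
#' @param terms Named list of [membership_function()]s, one per linguistic
#'   term.
#' @return Object of class `fuzzy_variable`.
#' @export
fuzzy_variable <- function(name, range, terms) {
  stopifnot(is.character(name), length(range) == 2, range[1] < range[2],
            length(terms) >= 1, !is.null(names(terms)),
            all(vapply(terms, inherits, logical(1), "membership_function")))
  structure(list(name = name, range = as.numeric(range), terms = terms),
            class = "fuzzy_variable")
}

#' Mamdani fuzzy-inference configuration
#'
#' Two inputs (`sensitivity`, `similarity`, both on 0..100) and one output
#' (`drift`, 0..100), with min-AND rule activation, clipped consequents,
#' pointwise-max aggregation and centre-of-gravity defuzzification.
#'
#' @param sensitivity,similarity,drift [fuzzy_variable()]s. `drift` is the
#'   output.
#' @param rules Data frame with character columns `sensitivity`, `similarity`,
#'   `drift`: each row reads "IF sensitivity IS \{term\} AND similarity IS
#'   \{term\} THEN drift IS \{term\}".
#' @param resolution Grid step for the defuzzification integral (default 0.1
#'   on the 0..100 drift range).
#' @return Object of class `fis_config`.
#' @seealso [default_fis()], [fis_assess()]
#' @export
fis_config <- function(sensitivity, similarity, drift, rules, resolution = 0.1) {
  stopifnot(inherits(sensitivity, "fuzzy_variable"),
            inherits(similarity, "fuzzy_variable"),
            inherits(drift, "fuzzy_variable"),
            is.data.frame(rules),
            all(c("sensitivity", "similarity", "drift") %in% names(rules)),
            resolution > 0)
  chk <- function(terms, var) {
    bad <- setdiff(terms, names(var$terms))
    if (length(bad)) stop("rule references unknown ", var$name, " term(s): ",
                          paste(bad, collapse = ", "))
  }
  chk(rules$sensitivity, sensitivity)
  chk(rules$similarity, similarity)
  chk(rules$drift, drift)
  structure(list(sensitivity = sensitivity, similarity = similarity,
                 drift = drift, rules = rules, resolution = resolution),
            class = "fis_config")
}

#' Default drift-assessment FIS
#'
#' The shipped expert configuration. Both inputs and the output use three
#' overlapping terms. Sensitivity and drift use
#' low/no_change = trapezoid (0,0,20,40), moderate = triangle (25,50,75),
#' high/change = trapezoid (60,80,100,100). The similarity terms are centred
#' on the mid-range where routine-change judgements are actually made:
#' low = trapezoid (0,0,30,50), moderate = triangle (30,50,70),
#' high = trapezoid (50,70,100,100). Nine rules form a severity table: low
#' similarity under high sensitivity asserts `change`, high similarity under
#' low sensitivity asserts `no_change`, with graded verdicts between.
#'
#' @param resolution Defuzzification grid step.
#' @return A [fis_config()].
#' @export
default_fis <- function(resolution = 0.1) {
  in_lo <- mf_trapezoid(0, 0, 20, 40)
  in_md <- mf_triangle(25, 50, 75)
  in_hi <- mf_trapezoid(60, 80, 100, 100)
  sim_lo <- mf_trapezoid(0, 0, 30, 50)
  sim_md <- mf_triangle(30, 50, 70)
  sim_hi <- mf_trapezoid(50, 70, 100, 100)
  rules <- data.frame(
    sensitivity = c("low", "moderate", "high",
                    "low", "moderate", "high",
                    "low", "moderate", "high"),
    similarity  = c("low", "low", "low",
                    "moderate", "moderate", "moderate",
                    "high", "high", "high"),
    drift       = c("moderate_change", "change", "change",
                    "no_change", "moderate_change", "change",
                    "no_change", "no_change", "moderate_change"),
    stringsAsFactors = FALSE
  )
  fis_config(
    sensitivity = fuzzy_variable("sensitivity", c(0, 100),
                                 list(low = in_lo, moderate = in_md, high = in_hi)),
    similarity = fuzzy_variable("similarity", c(0, 100),
                                list(low = sim_lo, moderate = sim_md, high = sim_hi)),
    drift = fuzzy_variable("drift", c(0, 100),
                           list(no_change = in_lo, moderate_change = in_md,
                                change = in_hi)),
    rules = rules,
    resolution = resolution
  )
}

.clamp_input <- function(x, var) {
  if (x < var$range[1] || x > var$range[2]) {
    warning(sprintf("%s = %g outside [%g, %g]; clamped", var$name, x,
                    var$range[1], var$range[2]))
    x <- min(max(x, var$range[1]), var$range[2])
  }
  x
}

#' Evaluate the rule base
#'
#' For each rule the activation is the minimum of the two input-term degrees;
#' the consequent term is clipped at the activation; the aggregate is the
#' pointwise maximum of the clipped consequents over a dense grid of the
#' output range.
#'
#' @param fis A [fis_config()].
#' @param sensitivity,similarity Crisp inputs (clamped to range with a
#'   warning if outside).
#' @return List with `x` (output grid) and `mu` (aggregated membership).
#' @export
evaluate_rules <- function(fis, sensitivity, similarity) {
  stopifnot(inherits(fis, "fis_config"))
  sensitivity <- .clamp_input(sensitivity, fis$sensitivity)
  similarity <- .clamp_input(similarity, fis$similarity)
  grid <- seq(fis$drift$range[1], fis$drift$range[2], by = fis$resolution)
  agg <- numeric(length(grid))
  for (i in seq_len(nrow(fis$rules))) {
    act <- min(
      membership(fis$sensitivity$terms[[fis$rules$sensitivity[i]]], sensitivity),
      membership(fis$similarity$terms[[fis$rules$similarity[i]]], similarity)
    )
    if (act <= 0) next
    clipped <- pmin(act, membership(fis$drift$terms[[fis$rules$drift[i]]], grid))
    agg <- pmax(agg, clipped)
  }
  list(x = grid, mu = agg)
}

#' Centre-of-gravity defuzzification
#'
#' \eqn{\int x \mu(x) dx / \int \mu(x) dx} approximated on the evaluation
#' grid. Invariant to uniform scaling of \eqn{\mu}.
#'
#' @param aggregate List with `x` and `mu` from [evaluate_rules()], or two
#'   numeric vectors via `x`/`mu` arguments.
#' @return The crisp output value.
#' @export
cog_defuzzify <- function(aggregate) {
  x <- aggregate$x
  mu <- aggregate$mu
  if (all(mu <= 0)) {
    stop("no rule fired: aggregated membership is identically zero (no verdict)")
  }
  sum(x * mu) / sum(mu)
}

#' Assess behavioural drift with the fuzzy system
#'
#' Runs the Mamdani pipeline for a specialist sensitivity and an observed
#' similarity (both on 0..100) and reports the defuzzified drift value plus
#' the membership degree of that value in each output term (the degrees need
#' not sum to 1; the sets overlap).
#'
#' @param fis A [fis_config()].
#' @param sensitivity,similarity Crisp inputs in 0..100.
#' @return Object of class `drift_assessment`: list with `crisp` and named
#'   `degrees`.
#' @export
fis_assess <- function(fis, sensitivity, similarity) {
  agg <- evaluate_rules(fis, sensitivity, similarity)
  crisp <- cog_defuzzify(agg)
  degrees <- vapply(fis$drift$terms, membership, numeric(1), x = crisp)
  structure(list(crisp = crisp, degrees = degrees), class = "drift_assessment")
}

#' @export
print.drift_assessment <- function(x, ...) {
  cat(sprintf("<drift_assessment: crisp %.2f | %s>\n", x$crisp,
              paste(sprintf("%s %.2f", names(x$degrees), x$degrees),
                    collapse = ", ")))
  invisible(x)
}

#' Verdict term of a drift assessment
#'
#' The output term in which the defuzzified value has the highest membership;
#' ties are broken toward the more severe term (term order in the output
#' variable is assumed mild-to-severe).
#'
#' @param assessment A `drift_assessment`.
#' @return The term name.
#' @export
drift_verdict <- function(assessment) {
  d <- assessment$degrees
  # which.max on the reversed vector prefers later (more severe) terms on ties
  names(d)[length(d) + 1 - which.max(rev(d))]
}

#' Load a FIS configuration from YAML or JSON
#'
#' The file mirrors the structure of [fis_config()]: a `variables` section
#' with `sensitivity`, `similarity` and `drift`, each holding `range` and
#' named `terms` as `(x, mu)` point lists (or `triangle`/`trapezoid`
#' shorthands), a `rules` list of `{sensitivity, similarity, drift}` term
#' triples, and an optional `resolution`.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A [fis_config()].
#' @export
read_fis_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  if (is.null(obj$variables) || is.null(obj$rules)) {
    stop("FIS config must have 'variables' and 'rules' sections: ", path)
  }
  parse_term <- function(tm, term_name) {
    if (!is.null(tm$triangle)) {
      v <- as.numeric(unlist(tm$triangle))
      if (length(v) != 3) stop("triangle needs 3 points in term ", term_name)
      return(mf_triangle(v[1], v[2], v[3]))
    }
    if (!is.null(tm$trapezoid)) {
      v <- as.numeric(unlist(tm$trapezoid))
      if (length(v) != 4) stop("trapezoid needs 4 points in term ", term_name)
      return(mf_trapezoid(v[1], v[2], v[3], v[4]))
    }
    if (!is.null(tm$points)) {
      pts <- tm$points
      x <- vapply(pts, function(p) as.numeric(p[[1]]), numeric(1))
      mu <- vapply(pts, function(p) as.numeric(p[[2]]), numeric(1))
      return(membership_function(x, mu))
    }
    stop("term ", term_name,
         " must define 'triangle', 'trapezoid' or 'points'")
  }
  parse_var <- function(v, name) {
    if (is.null(v$range) || is.null(v$terms)) {
      stop("variable ", name, " must define 'range' and 'terms'")
    }
    terms <- lapply(names(v$terms), function(tn) parse_term(v$terms[[tn]], tn))
    names(terms) <- names(v$terms)
    fuzzy_variable(name, as.numeric(unlist(v$range)), terms)
  }
  rules <- do.call(rbind, lapply(obj$rules, function(r) {
    if (is.null(r$sensitivity) || is.null(r$similarity) || is.null(r$drift)) {
      stop("each rule needs 'sensitivity', 'similarity' and 'drift' terms")
    }
    data.frame(sensitivity = r$sensitivity, similarity = r$similarity,
               drift = r$drift, stringsAsFactors = FALSE)
  }))
  fis_config(
    sensitivity = parse_var(obj$variables$sensitivity, "sensitivity"),
    similarity = parse_var(obj$variables$similarity, "similarity"),
    drift = parse_var(obj$variables$drift, "drift"),
    rules = rules,
    resolution = as.numeric(obj$resolution %||% 0.1)
  )
}

#' Calibrate the specialist sensitivity to a crisp threshold
#'
#' Finds the sensitivity input at which the fuzzy verdict flips from `change`
#' to a milder term exactly at a given similarity threshold, so that the fuzzy
#' and crisp decision rules agree at the boundary. The verdict boundary in
#' similarity is located by bisection for each sensitivity, and the
#' sensitivity is then chosen by grid-plus-bisection search.
#'
#' @param fis A [fis_config()].
#' @param threshold Crisp similarity threshold on `[0, 1]`.
#' @param tol Tolerance on the boundary location (similarity points, 0..100).
#' @return The calibrated sensitivity (0..100), with the achieved boundary as
#'   attribute `boundary`.
#' @export
calibrate_sensitivity <- function(fis, threshold, tol = 0.05) {
  stopifnot(threshold >= 0, threshold <= 1)
  target <- threshold * 100
  fires <- function(sens, sim) {
    v <- tryCatch(drift_verdict(fis_assess(fis, sens, sim)),
                  error = function(e) NA_character_)
    identical(v, "change")
  }
  # largest similarity (0..100) still judged "change" at this sensitivity
  boundary <- function(sens) {
    if (!fires(sens, 0)) return(-Inf)
    if (fires(sens, 100)) return(Inf)
    lo <- 0; hi <- 100
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (fires(sens, mid)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  sens_grid <- seq(0, 100, by = 2)
  bounds <- vapply(sens_grid, boundary, numeric(1))
  finite <- is.finite(bounds)
  if (!any(finite)) stop("no sensitivity yields a finite change boundary")
  i <- which.min(abs(bounds - target))
  best <- sens_grid[i]
  # refine around the best grid point (boundary is monotone locally)
  lo <- max(0, best - 2); hi <- min(100, best + 2)
  for (iter in 1:25) {
    mid <- (lo + hi) / 2
    b <- boundary(mid)
    if (!is.finite(b)) break
    if (abs(b - target) < tol) { best <- mid; break }
    # higher sensitivity widens the change region (raises the boundary)
    if (b < target) lo <- mid else hi <- mid
    best <- mid
  }
  structure(best, boundary = boundary(best))
}
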