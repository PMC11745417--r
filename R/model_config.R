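#' @importFrom stats setNames
NULL

.RIBONET_ROLES <- c("host_polymerase", "host_template", "parasite", "hyperparasite")
.RIBONET_YIELD_KINDS <- c("unit", "one_minus_mu", "mu", "beta")
.RIBONET_PRESET_IDS <- c("1", "2.1", "2.2", "3.1", "3.2", "3.0.1", "3.0.2")

#' Derive the Michaelis-constant matrix from elementary rate matrices
#'
#' For every enzyme--template pair (i, j) the Michaelis constant is
#' \deqn{K_M[i,j] = (k_{off}[i,j] + k_{cat}[i,j]) / k_{on}[i,j].}
#' Rows index the enzyme, columns the template. Association rates must be
#' strictly positive: pairs that should not form complexes are represented by
#' a small placeholder association rate (see [build_preset()]), never by zero,
#' so that the complex solver always works on the full n^2 system.
#'
#' @param kon n x n matrix of association rates (per concentration per time),
#'   all entries strictly positive.
#' @param koff n x n matrix of dissociation rates (per time), nonnegative.
#' @param kcat n x n matrix of catalytic turnover rates (per time), nonnegative.
#' @return n x n numeric matrix of Michaelis constants.
#' @examples
#' derive_km_matrix(kon = matrix(0.19), koff = matrix(0.1), kcat = matrix(0.08))
#' @export
derive_km_matrix <- function(kon, koff, kcat) {
  kon <- as.matrix(kon); koff <- as.matrix(koff); kcat <- as.matrix(kcat)
  if (!all(dim(kon) == dim(koff)) || !all(dim(kon) == dim(kcat))) {
    stop("kon, koff and kcat must have identical dimensions")
  }
  bad <- which(!(kon > 0), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("kon[%d,%d] = %g is not strictly positive; forbidden complexes must use a small positive placeholder rate",
                 bad[1, 1], bad[1, 2], kon[bad[1, 1], bad[1, 2]]))
  }
  if (any(koff < 0) || any(kcat < 0)) {
    stop("koff and kcat entries must be nonnegative")
  }
  (koff + kcat) / kon
}

#' Create a production rule
#'
#' A production rule states that the enzyme--template complex
#' `R[enzyme]_R[template]` catalytically produces species `product` at rate
#' `yield * kcat[enzyme, template] * complex * Pi`, where `Pi` is the habitat
#' restriction factor. The yield factor is symbolic so that rules stay correct
#' when the mutation rate or trigger strength of a model is changed:
#' `"unit"` resolves to 1, `"one_minus_mu"` to (1 - mu), `"mu"` to mu, and
#' `"beta"` to the hyperparasite trigger strength.
#'
#' @param enzyme,template 1-based species indices of the source complex.
#' @param product 1-based index of the species produced.
#' @param yield_kind one of `"unit"`, `"one_minus_mu"`, `"mu"`, `"beta"`.
#' @return one-row data frame with columns enzyme, template, product,
#'   yield_kind (the numeric yield is resolved by [model_spec()]).
#' @export
production_rule <- function(enzyme, template, product, yield_kind = "unit") {
  yield_kind <- match.arg(yield_kind, .RIBONET_YIELD_KINDS)
  data.frame(enzyme = as.integer(enzyme), template = as.integer(template),
             product = as.integer(product), yield_kind = yield_kind,
             stringsAsFactors = FALSE)
}

.resolve_yields <- function(rules, mu, beta) {
  vapply(rules$yield_kind, function(k) {
    switch(k,
           unit = 1.0,
           one_minus_mu = 1.0 - mu,
           mu = mu,
           beta = beta,
           stop("unknown yield kind: ", k))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Assemble a complete model specification
#'
#' Bundles species identities, rate matrices, production rules, habitat
#' parameters, initial concentrations and integration settings into a single
#' validated object; the Michaelis-constant matrix and the numeric rule yields
#' are derived fields, recomputed whenever the spec is rebuilt.
#'
#' All quantities are dimensionless model units. Indexing is 1-based
#' everywhere (species 1 is conventionally the ribozyme polymerase).
#'
#' @param names character vector of species labels (unique), e.g.
#'   `c("R1","R2","P","F")`.
#' @param roles per-species role, each one of `"host_polymerase"`,
#'   `"host_template"`, `"parasite"`, `"hyperparasite"`.
#' @param kon,koff,kcat n x n rate matrices (row = enzyme, column = template).
#' @param rules data frame of production rules, see [production_rule()].
#' @param decay per-species first-order decay rates d_i >= 0.
#' @param capacity habitat capacity K > 0 (maximum weighted RNA load).
#' @param capacity_weights per-species positive weights q_i; host species use
#'   1, smaller parasitic species use q > 1 because each molecule consumes
#'   fewer habitat resources.
#' @param mu polymerase mutation rate in `[0, 1)`; routes a mu-fraction of
#'   host replication output to the parasite.
#' @param alpha per-species constant inflow rates (nonzero only for the
#'   parasite in the shipped presets).
#' @param beta hyperparasite trigger strength: hyperparasites produced per
#'   catalytic replication event on a parasite template.
#' @param initials per-species initial total concentrations, nonnegative.
#' @param t_end integration horizon (> 0 unless a single-state run is wanted).
#' @param dt Euler time step, 0 < dt <= t_end when t_end > 0.
#' @param epsilon placeholder association rate for forbidden complexes.
#' @param eta placeholder dissociation rate for forbidden complexes.
#' @param name optional human-readable scenario label.
#' @return object of class `model_spec`.
#' @seealso [build_preset()], [validate_spec()], [integrate_model()]
#' @export
model_spec <- function(names, roles, kon, koff, kcat, rules,
                       decay, capacity, capacity_weights,
                       mu = 0, alpha = 0, beta = 0,
                       initials, t_end, dt = 0.1,
                       epsilon = 1e-5, eta = 0.1, name = NULL) {
  n <- length(names)
  kon <- as.matrix(kon); koff <- as.matrix(koff); kcat <- as.matrix(kcat)
  if (length(alpha) == 1L) alpha <- rep(as.numeric(alpha), n)
  if (length(decay) == 1L) decay <- rep(as.numeric(decay), n)
  if (length(capacity_weights) == 1L) capacity_weights <- rep(as.numeric(capacity_weights), n)
  spec <- structure(list(
    name = if (is.null(name)) "custom" else name,
    n = n,
    species = data.frame(name = as.character(names),
                         role = as.character(roles),
                         capacity_weight = as.numeric(capacity_weights),
                         stringsAsFactors = FALSE),
    kon = kon, koff = koff, kcat = kcat,
    km = NULL,
    rules = rules,
    decay = as.numeric(decay),
    capacity = as.numeric(capacity),
    mu = as.numeric(mu),
    alpha = as.numeric(alpha),
    beta = as.numeric(beta),
    initials = as.numeric(initials),
    t_end = as.numeric(t_end),
    dt = as.numeric(dt),
    epsilon = as.numeric(epsilon),
    eta = as.numeric(eta)
  ), class = "model_spec")
  refresh_spec(spec)
}

#' Recompute the derived fields of a model specification
#'
#' Re-derives the Michaelis-constant matrix and the numeric rule yields from
#' the primary fields. Called automatically by [model_spec()] and
#' [set_spec_value()]; call it yourself after editing a spec's fields
#' directly.
#'
#' @param spec a `model_spec`.
#' @return the spec with `km` and `rules$yield` up to date.
#' @export
refresh_spec <- function(spec) {
  spec$km <- derive_km_matrix(spec$kon, spec$koff, spec$kcat)
  spec$rules$yield <- .resolve_yields(spec$rules, spec$mu, spec$beta)
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec '%s'> %d species: %s\n", x$name, x$n,
              paste(x$species$name, collapse = ", ")))
  cat(sprintf("  roles: %s\n", paste(x$species$role, collapse = ", ")))
  cat(sprintf("  K = %g, mu = %g, alpha = (%s), beta = %g\n",
              x$capacity, x$mu, paste(x$alpha, collapse = ", "), x$beta))
  cat(sprintf("  t_end = %g, dt = %g, %d production rules\n",
              x$t_end, x$dt, nrow(x$rules)))
  invisible(x)
}

.host_rules <- function(routed) {
  # R1_R2 -> R1 and R1_R1 -> R2; with mutation routing a mu-fraction of each
  # catalytic event yields a parasite copy instead of the host product
  kind <- if (routed) "one_minus_mu" else "unit"
  rbind(production_rule(1, 2, 1, kind),
        production_rule(1, 1, 2, kind))
}

#' List the available model presets
#' @return character vector of preset identifiers.
#' @export
preset_ids <- function() .RIBONET_PRESET_IDS

#' Build one of the shipped model presets
#'
#' The presets cover the full model family, all in dimensionless units with
#' decay d = 0.005 for every species, capacity K = 20, host initials
#' (R1, R2) = (1, 1), dt = 0.1, and placeholder rates epsilon = 1e-5,
#' eta = 0.1 for complexes that should only ever form at negligible levels:
#'
#' * `"1"` -- host cycle only (n = 2): polymerase R1 replicates itself via
#'   template R2 (`kon = [[0.2, 0.19], [eps, eps]]`,
#'   `kcat = [[0.1, 0.08], [0, 0]]`, hence KM[1,1] = 1.0, KM[1,2] = 0.947).
#' * `"2.1"` -- adds a parasite template P (n = 3, `kon[1,3] = 0.2`,
#'   `kcat[1,3] = 0.1`, capacity weight q_P = 5) generated by mutation,
#'   mu = 0.01, no inflow.
#' * `"2.2"` -- as 2.1 but parasites flow in from outside: mu = 0,
#'   alpha_P = 0.005.
#' * `"3.1"` -- adds a hyperparasite F (n = 4, q_F = 10, mu = 0.01,
#'   alpha_P = 0.001, trigger beta = 1.5) that binds P and itself into futile
#'   complexes with `kon[3,4] = kon[4,4] = 0.1` (KM = 1.0, micromolar range).
#' * `"3.2"` -- as 3.1 with tighter binding `kon[3,4] = kon[4,4] = 1.0`
#'   (KM = 0.1).
#' * `"3.0.1"` / `"3.0.2"` -- alternative hyperparasite variants with the
#'   same binding as 3.1 / 3.2 but residual catalysis
#'   `kcat[3,4] = kcat[4,4] = 0.04` producing F (KM = 1.4 and 0.14).
#'
#' @param model_id preset identifier, one of
#'   `"1", "2.1", "2.2", "3.1", "3.2", "3.0.1", "3.0.2"` (numeric forms such
#'   as `1` or `2.1` are accepted).
#' @return a fully populated [model_spec()].
#' @examples
#' spec <- build_preset("3.1")
#' spec$km[3, 4]  # Michaelis constant of the P_F futile complex
#' @export
build_preset <- function(model_id) {
  id <- as.character(model_id)
  if (id == "2") id <- "2.1"
  if (id == "3") id <- "3.1"
  if (!id %in% .RIBONET_PRESET_IDS) {
    stop(sprintf("unknown model id '%s'; valid ids: %s", id,
                 paste(.RIBONET_PRESET_IDS, collapse = ", ")))
  }
  eps <- 1e-5; eta <- 0.1
  d <- 0.005; K <- 20

  if (id == "1") {
    kon <- matrix(c(0.2, 0.19,
                    eps, eps), 2, 2, byrow = TRUE)
    koff <- matrix(eta, 2, 2)
    kcat <- matrix(c(0.1, 0.08,
                     0, 0), 2, 2, byrow = TRUE)
    return(model_spec(
      names = c("R1", "R2"),
      roles = c("host_polymerase", "host_template"),
      kon = kon, koff = koff, kcat = kcat,
      rules = .host_rules(routed = FALSE),
      decay = d, capacity = K, capacity_weights = c(1, 1),
      mu = 0, alpha = c(0, 0), beta = 0,
      initials = c(1, 1), t_end = 1000, dt = 0.1,
      epsilon = eps, eta = eta, name = "model 1"))
  }

  if (id %in% c("2.1", "2.2")) {
    kon <- matrix(eps, 3, 3)
    kon[1, ] <- c(0.2, 0.19, 0.2)
    koff <- matrix(eta, 3, 3)
    kcat <- matrix(0, 3, 3)
    kcat[1, ] <- c(0.1, 0.08, 0.1)
    rules <- rbind(.host_rules(routed = TRUE),
                   production_rule(1, 3, 3, "unit"),
                   production_rule(1, 2, 3, "mu"),
                   production_rule(1, 1, 3, "mu"))
    mu <- if (id == "2.1") 0.01 else 0
    alphaP <- if (id == "2.1") 0 else 0.005
    return(model_spec(
      names = c("R1", "R2", "P"),
      roles = c("host_polymerase", "host_template", "parasite"),
      kon = kon, koff = koff, kcat = kcat, rules = rules,
      decay = d, capacity = K, capacity_weights = c(1, 1, 5),
      mu = mu, alpha = c(0, 0, alphaP), beta = 0,
      initials = c(1, 1, 0), t_end = 5000, dt = 0.1,
      epsilon = eps, eta = eta, name = paste("model", id)))
  }

  # model 3 family (n = 4)
  kon_hp <- if (id %in% c("3.1", "3.0.1")) 0.1 else 1.0
  kcat_hp <- if (id %in% c("3.0.1", "3.0.2")) 0.04 else 0
  kon <- matrix(eps, 4, 4)
  kon[1, ] <- c(0.2, 0.19, 0.2, eps)
  kon[3, 4] <- kon_hp
  kon[4, 4] <- kon_hp
  koff <- matrix(eta, 4, 4)
  kcat <- matrix(0, 4, 4)
  kcat[1, ] <- c(0.1, 0.08, 0.1, 0)
  kcat[3, 4] <- kcat_hp
  kcat[4, 4] <- kcat_hp
  rules <- rbind(.host_rules(routed = TRUE),
                 production_rule(1, 3, 3, "unit"),
                 production_rule(1, 2, 3, "mu"),
                 production_rule(1, 1, 3, "mu"),
                 production_rule(1, 3, 4, "beta"))
  if (kcat_hp > 0) {
    # residual hyperparasite catalysis: P_F and F_F complexes produce F copies
    rules <- rbind(rules,
                   production_rule(3, 4, 4, "unit"),
                   production_rule(4, 4, 4, "unit"))
  }
  model_spec(
    names = c("R1", "R2", "P", "F"),
    roles = c("host_polymerase", "host_template", "parasite", "hyperparasite"),
    kon = kon, koff = koff, kcat = kcat, rules = rules,
    decay = d, capacity = K, capacity_weights = c(1, 1, 5, 10),
    mu = 0.01, alpha = c(0, 0, 0.001, 0), beta = 1.5,
    initials = c(1, 1, 0, 0), t_end = 2000, dt = 0.1,
    epsilon = eps, eta = eta, name = paste("model", id))
}

.finding <- function(severity, field, message) {
  data.frame(severity = severity, field = field, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a model specification
#'
#' Checks structural and physical invariants (matrix shapes, rate positivity,
#' Michaelis-constant consistency, parameter ranges, rule index validity) and
#' returns findings rather than throwing: a zero-row data frame means the spec
#' is clean. All shipped presets validate clean.
#'
#' @param spec a `model_spec`.
#' @return data frame with columns `severity` (`"error"`/`"warning"`),
#'   `field` and `message`; zero rows when nothing is wrong.
#' @export
validate_spec <- function(spec) {
  out <- .finding(character(), character(), character())
  n <- spec$n
  add <- function(sev, field, msg) out <<- rbind(out, .finding(sev, field, msg))

  if (n < 1) add("error", "species", "at least one species is required")
  if (anyDuplicated(spec$species$name)) add("error", "species", "species names must be unique")
  if (!all(spec$species$role %in% .RIBONET_ROLES)) {
    add("error", "species", sprintf("roles must be in {%s}", paste(.RIBONET_ROLES, collapse = ", ")))
  }
  if (!all(spec$species$capacity_weight > 0)) add("error", "capacity_weights", "capacity weights must be > 0")

  for (m in c("kon", "koff", "kcat", "km")) {
    if (!all(dim(spec[[m]]) == c(n, n))) add("error", m, sprintf("%s must be %d x %d", m, n, n))
  }
  bad <- which(!(spec$kon > 0), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    add("error", "kon", sprintf("kon[%d,%d] must be strictly positive (use the epsilon placeholder for forbidden complexes)",
                                bad[1, 1], bad[1, 2]))
  } else {
    km_expect <- (spec$koff + spec$kcat) / spec$kon
    if (max(abs(spec$km - km_expect)) > 1e-12 * max(1, max(abs(km_expect)))) {
      add("error", "km", "km is inconsistent with (koff + kcat)/kon; call refresh_spec()")
    }
  }
  if (any(spec$koff < 0)) add("error", "koff", "koff entries must be nonnegative")
  if (any(spec$kcat < 0)) add("error", "kcat", "kcat entries must be nonnegative")

  if (!(spec$capacity > 0)) add("error", "capacity", "capacity K must be > 0")
  if (spec$mu < 0 || spec$mu >= 1) add("error", "mu", "mutation rate mu must lie in [0, 1)")
  if (spec$beta < 0) add("error", "beta", "trigger strength beta must be >= 0")
  if (any(spec$decay < 0)) add("error", "decay", "decay rates must be >= 0")
  if (any(spec$alpha < 0)) add("error", "alpha", "inflow rates must be >= 0")
  if (length(spec$initials) != n) add("error", "initials", sprintf("initials must have length %d", n))
  if (any(spec$initials < 0)) add("error", "initials", "initial concentrations must be >= 0")
  if (!(spec$dt > 0)) add("error", "dt", "dt must be > 0")
  if (spec$t_end < 0) add("error", "t_end", "t_end must be >= 0")
  if (spec$t_end > 0 && spec$dt > spec$t_end) add("error", "dt", "dt must not exceed t_end")

  r <- spec$rules
  if (nrow(r) > 0) {
    idx_ok <- all(r$enzyme %in% seq_len(n)) && all(r$template %in% seq_len(n)) &&
      all(r$product %in% seq_len(n))
    if (!idx_ok) add("error", "rules", "rule indices must lie in 1..n")
    if (any(r$yield < 0)) add("error", "rules", "rule yields must be >= 0")
  }
  out
}

# ---- configuration file I/O --------------------------------------------

.matrix_to_rows <- function(m) lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
.rows_to_matrix <- function(rows) do.call(rbind, lapply(rows, as.numeric))

#' Write a model specification to a YAML configuration file
#'
#' Matrices are written row-major (row = enzyme, column = template);
#' production rules keep their symbolic yield kinds so that mu/beta edits in
#' the file stay consistent. [read_model_config()] restores an equal spec.
#'
#' @param spec a `model_spec`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(spec, path) {
  cfg <- list(
    name = spec$name,
    species = as.character(spec$species$name),
    roles = as.character(spec$species$role),
    capacity_weights = as.numeric(spec$species$capacity_weight),
    kon = .matrix_to_rows(spec$kon),
    koff = .matrix_to_rows(spec$koff),
    kcat = .matrix_to_rows(spec$kcat),
    rules = lapply(seq_len(nrow(spec$rules)), function(k) {
      list(enzyme = spec$rules$enzyme[k], template = spec$rules$template[k],
           product = spec$rules$product[k], yield_kind = spec$rules$yield_kind[k])
    }),
    decay = spec$decay,
    capacity = spec$capacity,
    mu = spec$mu,
    alpha = spec$alpha,
    beta = spec$beta,
    initials = spec$initials,
    t_end = spec$t_end,
    dt = spec$dt,
    epsilon = spec$epsilon,
    eta = spec$eta
  )
  writeLines(yaml::as.yaml(cfg, precision = 15), path)
  invisible(path)
}

#' Read a model specification from a YAML configuration file
#'
#' @param path file written by [write_model_config()] (or hand-authored in
#'   the same layout).
#' @return a `model_spec` with derived fields recomputed.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("species", "roles", "kon", "koff", "kcat", "rules", "decay",
                "capacity", "capacity_weights", "initials", "t_end", "dt")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0) {
    stop("configuration file is missing keys: ", paste(missing, collapse = ", "))
  }
  rules <- do.call(rbind, lapply(cfg$rules, function(r) {
    production_rule(r$enzyme, r$template, r$product, r$yield_kind)
  }))
  model_spec(
    names = cfg$species, roles = cfg$roles,
    kon = .rows_to_matrix(cfg$kon), koff = .rows_to_matrix(cfg$koff),
    kcat = .rows_to_matrix(cfg$kcat), rules = rules,
    decay = cfg$decay, capacity = cfg$capacity,
    capacity_weights = cfg$capacity_weights,
    mu = if (is.null(cfg$mu)) 0 else cfg$mu,
    alpha = if (is.null(cfg$alpha)) 0 else cfg$alpha,
    beta = if (is.null(cfg$beta)) 0 else cfg$beta,
    initials = cfg$initials, t_end = cfg$t_end, dt = cfg$dt,
    epsilon = if (is.null(cfg$epsilon)) 1e-5 else cfg$epsilon,
    eta = if (is.null(cfg$eta)) 0.1 else cfg$eta,
    name = if (is.null(cfg$name)) "config" else cfg$name)
}

# ---- spec overrides -----------------------------------------------------

.OVERRIDE_FIELDS <- c("kon", "koff", "kcat", "decay", "alpha", "initials",
                      "capacity_weights", "capacity", "mu", "beta", "t_end",
                      "dt", "epsilon", "eta")

#' Set one parameter of a model specification by path
#'
#' Paths address either scalars (`"mu"`, `"t_end"`), vector entries
#' (`"alpha[3]"`, `"initials[1]"`) or matrix entries (`"kon[3,4]"`), all
#' 1-based. A bare `"alpha"` with a scalar value sets the inflow of the
#' parasite species (the only species with inflow in the presets). Derived
#' fields (Michaelis constants, numeric rule yields) are refreshed.
#'
#' @param spec a `model_spec`.
#' @param path parameter path string.
#' @param value numeric replacement value.
#' @return the updated spec.
#' @examples
#' spec <- set_spec_value(build_preset("2.1"), "mu", 0)
#' @export
set_spec_value <- function(spec, path, value) {
  m <- regmatches(path, regexec("^([a-z_]+)(\\[([0-9]+)(,([0-9]+))?\\])?$", path))[[1]]
  if (length(m) == 0 || !(m[2] %in% .OVERRIDE_FIELDS)) {
    stop(sprintf("unknown parameter path '%s'; valid fields: %s (optionally with [i] or [i,j])",
                 path, paste(.OVERRIDE_FIELDS, collapse = ", ")))
  }
  field <- m[2]
  i <- if (nzchar(m[4])) as.integer(m[4]) else NA_integer_
  j <- if (length(m) >= 6 && nzchar(m[6])) as.integer(m[6]) else NA_integer_
  value <- as.numeric(value)

  vec_fields <- c("decay", "alpha", "initials", "capacity_weights")
  mat_fields <- c("kon", "koff", "kcat")
  get_field <- function() {
    if (field == "capacity_weights") spec$species$capacity_weight else spec[[field]]
  }
  set_field <- function(v) {
    if (field == "capacity_weights") spec$species$capacity_weight <<- v else spec[[field]] <<- v
  }

  if (field %in% mat_fields) {
    if (is.na(i) || is.na(j)) stop(sprintf("'%s' needs a [i,j] index", field))
    if (i > spec$n || j > spec$n) stop(sprintf("index [%d,%d] out of range for n = %d", i, j, spec$n))
    v <- get_field(); v[i, j] <- value; set_field(v)
  } else if (field %in% vec_fields) {
    v <- get_field()
    if (!is.na(i)) {
      if (i > spec$n) stop(sprintf("index [%d] out of range for n = %d", i, spec$n))
      v[i] <- value
    } else if (length(value) == spec$n) {
      v <- value
    } else if (field == "alpha") {
      p <- which(spec$species$role == "parasite")
      if (length(p) == 0) stop("scalar 'alpha' override requires a parasite species; use alpha[i]")
      v[] <- 0; v[p] <- value
    } else {
      v[] <- value
    }
    set_field(v)
  } else {
    if (!is.na(i)) stop(sprintf("'%s' is scalar and takes no index", field))
    set_field(value)
  }
  refresh_spec(spec)
}
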