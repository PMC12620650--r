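#' Declarative demographic models
#'
#' A demographic model is a population tree with events, all expressed in
#' backward time from the present in generations: leaf populations with
#' present-day diploid effective sizes, divergence events (a derived
#' population's lineages join an ancestral population), transient size
#' changes (bottlenecks), continuous migration between coexisting
#' populations, and instantaneous admixture pulses.  Any numeric slot
#' (times, sizes, rates, fractions) may instead hold the name of a free
#' parameter; [bind_params()] substitutes values before simulation.
#'
#' @param populations tibble with columns `name`, `size` (present-day
#'   diploid N_e; numeric or parameter name).
#' @param splits tibble with columns `time`, `derived`, `ancestral`, `size`
#'   (N_e of the ancestral population from `time` backwards).
#' @param size_changes tibble with columns `pop`, `t_start`, `t_end`, `size`
#'   (a bottleneck is one such segment); may be `NULL`.
#' @param migrations tibble with columns `from`, `to`, `rate`, `t_start`,
#'   `t_end`: continuous backward migration (a lineage sampled in `from`
#'   traces its ancestry to `to` at `rate` per generation); may be `NULL`.
#' @param pulses tibble with columns `time`, `from`, `to`, `frac`; may be
#'   `NULL`.
#' @param mu mutation rate per site per generation.
#' @param gen_time generation time in years.
#' @return an object of class `demog_model`.
#' @export
demog_model <- function(populations, splits, size_changes = NULL,
                        migrations = NULL, pulses = NULL,
                        mu = 1.25e-8, gen_time = 29) {
  empty_seg <- tibble(pop = character(), t_start = numeric(),
                      t_end = numeric(), size = numeric())
  empty_mig <- tibble(from = character(), to = character(), rate = numeric(),
                      t_start = numeric(), t_end = numeric())
  empty_pulse <- tibble(time = numeric(), from = character(),
                        to = character(), frac = numeric())
  m <- structure(list(
    populations = as_tibble(populations),
    splits = as_tibble(splits),
    size_changes = if (is.null(size_changes)) empty_seg else as_tibble(size_changes),
    migrations = if (is.null(migrations)) empty_mig else as_tibble(migrations),
    pulses = if (is.null(pulses)) empty_pulse else as_tibble(pulses),
    mu = mu, gen_time = gen_time
  ), class = "demog_model")
  m
}

#' @export
print.demog_model <- function(x, ...) {
  cat("<demog_model> ", nrow(x$populations), " leaf populations, ",
      nrow(x$splits), " divergences, ", nrow(x$migrations),
      " migration edges, ", nrow(x$size_changes), " size segments\n", sep = "")
  cat("  mu =", x$mu, " gen_time =", x$gen_time, "y\n")
  invisible(x)
}

# Resolve a slot that may hold a number, a free-parameter name, or the
# offset form "name+<number>" (used for bottleneck end times tied to a free
# split time).
resolve_slot <- function(x, theta) {
  if (is.numeric(x)) return(as.numeric(x))
  vapply(as.character(x), function(v) {
    if (is.na(v)) return(NA_real_)
    if (!is.na(suppressWarnings(num <- as.numeric(v)))) return(num)
    off <- 0
    if (grepl("+", v, fixed = TRUE)) {
      parts <- strsplit(v, "+", fixed = TRUE)[[1]]
      v <- trimws(parts[1]); off <- as.numeric(parts[2])
    }
    if (!v %in% names(theta))
      abort(paste0("unbound parameter '", v, "'"))
    as.numeric(theta[[v]]) + off
  }, numeric(1), USE.NAMES = FALSE)
}

#' Bind free parameters of a demographic model
#'
#' Substitutes numeric values for every named free parameter, returning a
#' fully numeric model ready for validation and simulation.
#'
#' @param model a `demog_model`.
#' @param theta named numeric vector or list of parameter values.
#' @return a `demog_model` with all slots numeric.
#' @export
bind_params <- function(model, theta = numeric()) {
  m <- model
  m$populations$size <- resolve_slot(m$populations$size, theta)
  if (nrow(m$splits)) {
    m$splits$time <- resolve_slot(m$splits$time, theta)
    m$splits$size <- resolve_slot(m$splits$size, theta)
  }
  if (nrow(m$size_changes)) {
    m$size_changes$t_start <- resolve_slot(m$size_changes$t_start, theta)
    m$size_changes$t_end <- resolve_slot(m$size_changes$t_end, theta)
    m$size_changes$size <- resolve_slot(m$size_changes$size, theta)
  }
  if (nrow(m$migrations)) {
    m$migrations$rate <- resolve_slot(m$migrations$rate, theta)
    m$migrations$t_start <- resolve_slot(m$migrations$t_start, theta)
    m$migrations$t_end <- resolve_slot(m$migrations$t_end, theta)
  }
  if (nrow(m$pulses)) {
    m$pulses$time <- resolve_slot(m$pulses$time, theta)
    m$pulses$frac <- resolve_slot(m$pulses$frac, theta)
  }
  m
}

#' Names of free parameters appearing in a model
#' @param model a `demog_model`.
#' @return character vector of unbound parameter names.
#' @export
free_params <- function(model) {
  chr <- c(model$populations$size,
           if (nrow(model$splits)) c(model$splits$time, model$splits$size),
           if (nrow(model$size_changes)) c(model$size_changes$t_start,
                                           model$size_changes$t_end,
                                           model$size_changes$size),
           if (nrow(model$migrations)) c(model$migrations$rate),
           if (nrow(model$pulses)) c(model$pulses$time, model$pulses$frac))
  chr <- as.character(chr[!is.na(chr)])
  chr <- chr[is.na(suppressWarnings(as.numeric(chr)))]
  unique(trimws(sub("\\+.*$", "", chr)))
}

# Time at which a population merges into its ancestor (Inf for the root side).
merge_times <- function(model) {
  mt <- setNames(rep(Inf, nrow(model$populations)), model$populations$name)
  anc <- setdiff(model$splits$ancestral, names(mt))
  mt <- c(mt, setNames(rep(Inf, length(anc)), anc))
  for (i in seq_len(nrow(model$splits)))
    mt[model$splits$derived[i]] <- model$splits$time[i]
  mt
}

#' Validate a demographic model
#'
#' Checks structural invariants: positive sizes, non-negative topologically
#' ordered event times, pulse fractions in (0,1), positive mutation rate and
#' generation time, no migration between populations after they have merged,
#' and reachability (all populations coalesce to a single root).
#'
#' @param model a fully bound `demog_model` (see [bind_params()]).
#' @return character vector of violations; empty if the model is valid.
#' @export
validate_model <- function(model) {
  v <- character()
  p <- model$populations
  if (anyDuplicated(p$name)) v <- c(v, "duplicate population name")
  if (any(!is.finite(p$size) | p$size <= 0))
    v <- c(v, "nonpositive size: leaf population")
  s <- model$splits
  if (nrow(s)) {
    if (any(!is.finite(s$time) | s$time < 0)) v <- c(v, "negative split time")
    if (any(!is.na(s$size) & s$size <= 0))
      v <- c(v, "nonpositive size: ancestral population")
  }
  if (!is.finite(model$mu) || model$mu <= 0) v <- c(v, "nonpositive mutation rate")
  if (!is.finite(model$gen_time) || model$gen_time <= 0)
    v <- c(v, "nonpositive generation time")
  if (nrow(model$pulses) &&
      any(model$pulses$frac <= 0 | model$pulses$frac >= 1))
    v <- c(v, "pulse fraction outside (0,1)")
  if (nrow(model$size_changes) &&
      any(model$size_changes$size <= 0))
    v <- c(v, "nonpositive size: size-change segment")
  # reachability: union-find over splits
  all_pops <- unique(c(p$name, s$derived, s$ancestral))
  parent <- setNames(all_pops, all_pops)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  if (nrow(s)) for (i in seq_len(nrow(s))) {
    a <- find(s$derived[i]); b <- find(s$ancestral[i])
    if (a != b) parent[[a]] <- b
  }
  roots <- unique(vapply(p$name, find, character(1)))
  if (length(roots) > 1) v <- c(v, "disconnected: populations never merge")
  # topological ordering: an ancestor must merge later than its derived pops
  mt <- merge_times(model)
  if (nrow(s)) for (i in seq_len(nrow(s))) {
    if (is.finite(mt[s$ancestral[i]]) && mt[s$ancestral[i]] < s$time[i] - 1e-9)
      v <- c(v, sprintf("ordering: %s merges before its derived %s",
                        s$ancestral[i], s$derived[i]))
  }
  # migration epochs must end by the earlier merge of the two endpoints
  mg <- model$migrations
  if (nrow(mg)) for (i in seq_len(nrow(mg))) {
    lim <- min(mt[mg$from[i]], mt[mg$to[i]], na.rm = TRUE)
    if (mg$t_start[i] >= lim)
      v <- c(v, sprintf("migration %s->%s starts after merge",
                        mg$from[i], mg$to[i]))
  }
  v
}

#' Convert calendar time to generations
#'
#' @param t_years time in years.
#' @param g generation time in years per generation.
#' @return real-valued number of generations (`t_years / g`).
#' @export
years_to_generations <- function(t_years, g = 29) {
  stopifnot(g > 0)
  t_years / g
}

#' Convert generations to thousands of years (kya)
#' @param t_gen time in generations.
#' @param g generation time in years.
#' @return time in kya.
#' @export
generations_to_kya <- function(t_gen, g = 29) t_gen * g / 1000

# ---- flattening for the coalescent engine ------------------------------

# Internal: turn a bound model + named haploid sample sizes into the event
# table consumed by the C++ simulator.
flatten_model <- function(model, sample_sizes) {
  viol <- validate_model(model)
  if (length(viol)) abort(paste("invalid model:", paste(viol, collapse = "; ")))
  leaves <- model$populations$name
  anc <- setdiff(unique(model$splits$ancestral), leaves)
  pops <- c(leaves, anc)
  idx <- setNames(seq_along(pops) - 1L, pops)
  samp <- integer(length(pops))
  for (nm in names(sample_sizes)) {
    if (!nm %in% leaves) abort(paste0("sampled population '", nm, "' not in model"))
    samp[idx[[nm]] + 1L] <- as.integer(sample_sizes[[nm]])
  }
  init <- numeric(length(pops))
  init[seq_along(leaves)] <- model$populations$size
  ev <- list()
  add <- function(time, type, a = 0L, b = 0L, x = 0) {
    ev[[length(ev) + 1L]] <<- c(time, type, a, b, x)
  }
  s <- model$splits
  anc_size <- setNames(rep(NA_real_, length(pops)), pops)
  if (nrow(s)) for (i in seq_len(nrow(s))) {
    add(s$time[i], 0L, idx[[s$derived[i]]], idx[[s$ancestral[i]]])
    if (!is.na(s$size[i])) {
      add(s$time[i], 1L, idx[[s$ancestral[i]]], 0L, s$size[i])
      if (is.na(anc_size[s$ancestral[i]]))
        anc_size[s$ancestral[i]] <- s$size[i]
    }
  }
  for (nm in anc)
    init[idx[[nm]] + 1L] <- if (is.na(anc_size[nm])) 1e4 else anc_size[nm]
  sc <- model$size_changes
  if (nrow(sc)) for (i in seq_len(nrow(sc))) {
    p <- sc$pop[i]
    base <- if (p %in% leaves) {
      model$populations$size[match(p, leaves)]
    } else anc_size[p]
    add(sc$t_start[i], 1L, idx[[p]], 0L, sc$size[i])
    if (is.finite(sc$t_end[i])) add(sc$t_end[i], 1L, idx[[p]], 0L, base)
  }
  mg <- model$migrations
  if (nrow(mg)) for (i in seq_len(nrow(mg))) {
    add(mg$t_start[i], 2L, idx[[mg$from[i]]], idx[[mg$to[i]]], mg$rate[i])
    if (is.finite(mg$t_end[i]))
      add(mg$t_end[i], 2L, idx[[mg$from[i]]], idx[[mg$to[i]]], 0)
  }
  pu <- model$pulses
  if (nrow(pu)) for (i in seq_len(nrow(pu)))
    add(pu$time[i], 3L, idx[[pu$from[i]]], idx[[pu$to[i]]], pu$frac[i])
  em <- do.call(rbind, ev)
  if (is.null(em)) em <- matrix(numeric(), ncol = 5)
  # stable sort by time, size/migration changes applied before merges at ties
  ord <- order(em[, 1], em[, 2] == 0)
  em <- em[ord, , drop = FALSE]
  list(n_pops = length(pops), pops = pops, samp = samp, init = init,
       events = em)
}

# ---- model config round trip -------------------------------------------

#' Write a demographic model to a YAML config file
#'
#' The config stores populations, events and rates; time slots may be given
#' in generations (as stored) and free parameters are kept by name, so a
#' written model reads back identically.
#'
#' @param model a `demog_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  to_chr <- function(d) lapply(seq_len(nrow(d)), function(i)
    lapply(as.list(d[i, ]), function(x) if (is.numeric(x)) x else as.character(x)))
  cfg <- list(
    populations = to_chr(model$populations),
    splits = to_chr(model$splits),
    size_changes = to_chr(model$size_changes),
    migrations = to_chr(model$migrations),
    pulses = to_chr(model$pulses),
    mu = model$mu, gen_time = model$gen_time
  )
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Read a demographic model from a YAML config file
#' @param path config file written by [write_model_config()] (or hand-edited
#'   to the same schema).
#' @return a `demog_model`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  tb <- function(x, template) {
    if (length(x) == 0) return(NULL)
    dplyr::bind_rows(lapply(x, as_tibble))
  }
  demog_model(populations = tb(cfg$populations),
              splits = tb(cfg$splits),
              size_changes = tb(cfg$size_changes),
              migrations = tb(cfg$migrations),
              pulses = tb(cfg$pulses),
              mu = cfg$mu, gen_time = cfg$gen_time)
}
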