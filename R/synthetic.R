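#' Synthetic study fixtures with known truth
#'
#' Generators that emulate the shapes of a multi-population human WGS
#' study — genotype panels simulated under the best-supported demographic
#' model, and allele-frequency panels for admixture-weight recovery — so
#' that every pipeline stage runs with no external data and every
#' recoverable quantity has a recorded generating value ("truth ledger").
#'
#' @name synthetic_data
NULL

scale_genome_length <- function(scale) {
  switch(scale,
         mini = 5e6,      # ~1e4 polymorphic sites
         desk = 1e8,      # ~2e5 polymorphic sites
         paper = 1.3e9,   # ~2.7e6 polymorphic sites
         abort("scale must be one of mini, desk, paper"))
}

#' Genotype fixture under the best-fit demographic scenario
#'
#' Simulates the six-population best-fit topology (nested Tibetan clade
#' plus a Yi/Mosuo clade and a Han lineage, bottleneck on the ancestral
#' Tibeto-Burman branch) and the four-population baseline scenario, with
#' the study system's published split times as generating truth and
#' documented defaults elsewhere (see [scenario_library()]).  Sample
#' sizes: 5 diploids per Tibeto-Burman population and 4 per Han
#' population (6-population panel), 4 per population in the 4-population
#' panel: large enough for the joint SFS to resolve the within-clade
#' split times at desk scale, small enough for low-count masking to leave
#' well-estimated cells.
#'
#' @param scale `"mini"` (~1e4 polymorphic sites), `"desk"` (~2e5) or
#'   `"paper"` (~2.7e6).
#' @param seed integer seed; fixtures are bit-reproducible from
#'   (model, scale, seed).
#' @param dir optional directory; when given, VCF, EIGENSTRAT, `.obs` SFS
#'   files and a JSON truth ledger are written there.
#' @return list with `g6`, `g4` (geno_matrix), `panel6`, `panel4`,
#'   `obs6`, `obs4` (joint_sfs) and `ledger`.
#' @export
make_sfs_study_fixture <- function(scale = c("mini", "desk", "paper"),
                                   seed = 1, dir = NULL) {
  scale <- match.arg(scale)
  L <- scale_genome_length(scale)
  scn6 <- scenario_library("ext_tb_with_tibetan")
  scn4 <- scenario_library("base_common_origin")
  ss6 <- setNames(c(4, 5, 5, 5, 5, 5), scn6$model$populations$name)
  ss4 <- setNames(rep(4, 4), scn4$model$populations$name)
  g6 <- simulate_genotypes(sim_spec(scn6$model, scn6$truth, sample_sizes = ss6,
                                    length = L, seed = derive_seed(seed, 61)))
  g4 <- simulate_genotypes(sim_spec(scn4$model, scn4$truth, sample_sizes = ss4,
                                    length = L, seed = derive_seed(seed, 62)))
  panel6 <- population_panel(names(ss6), 2L * ss6)
  panel4 <- population_panel(names(ss4), 2L * ss4)
  obs6 <- build_joint_sfs(g6, panel6)
  obs4 <- build_joint_sfs(g4, panel4)
  gt <- scn6$model$gen_time
  ledger <- list(
    scale = scale, seed = seed, genome_length = L,
    scenario_6pop = "ext_tb_with_tibetan", scenario_4pop = "base_common_origin",
    truth_generations = list(pop6 = as.list(scn6$truth),
                             pop4 = as.list(scn4$truth)),
    truth_kya = list(pop6 = as.list(generations_to_kya(scn6$truth, gt)),
                     pop4 = as.list(generations_to_kya(scn4$truth, gt))),
    n_sites = list(pop6 = n_sites(g6), pop4 = n_sites(g4)),
    files = list())
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    p <- function(...) file.path(dir, paste0(...))
    write_genotypes(g6, p("pop6_", scale, ".vcf"), "vcf")
    write_genotypes(g4, p("pop4_", scale, ".vcf"), "vcf")
    write_genotypes(g6, p("pop6_", scale), "eigenstrat")
    write_obs_sfs(obs6, p("pop6_", scale, ".obs"))
    write_obs_sfs(obs4, p("pop4_", scale, ".obs"))
    ledger$files <- list(
      vcf6 = p("pop6_", scale, ".vcf"), vcf4 = p("pop4_", scale, ".vcf"),
      obs6 = p("pop6_", scale, ".obs"), obs4 = p("pop4_", scale, ".obs"))
    jsonlite::write_json(ledger, p("truth_", scale, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(g6 = g6, g4 = g4, panel6 = panel6, panel4 = panel4,
       obs6 = obs6, obs4 = obs4, ledger = ledger)
}

#' Default mixing proportions for the three-way admixture fixture
#'
#' Majority source fixed at the published lower-bound weight of the
#' northern (millet-farmer related) source, the remainder split between
#' the coastal-southern and western-steppe sources in the ratio of their
#' published lower bounds.
#'
#' @return named numeric vector summing to 1.
#' @export
default_threeway_alphas <- function() {
  minor <- c(Taiwan_Hanben = 6.2, Russia_Sarmatian = 4.5)
  c(Lajia_LN = 0.807, minor / sum(minor) * (1 - 0.807))
}

#' Default mixing proportions for the two-way admixture fixture
#' @return named numeric vector summing to 1 (northern source at its
#'   published lower-bound weight).
#' @export
default_twoway_alphas <- function() {
  c(Miaozigou_MN = 0.857, Hoabinhian = 1 - 0.857)
}

#' Allele-frequency fixture for qpAdm recovery
#'
#' Builds a drift tree with diverged source lineages, seven outgroup
#' surrogates (named after the study system's canonical right set) and one
#' target mixed from the sources' pre-drift ancestors with the requested
#' proportions, followed by mild terminal drift.  Ancient sources are
#' emulated as extra-drifted populations with smaller sampled allele
#' counts; no sequencing damage or pseudo-haploid sampling is simulated.
#'
#' @param n_sites number of independent sites.
#' @param alphas named mixing proportions (2 or 3 sources, summing to 1);
#'   defaults to [default_threeway_alphas()].
#' @param seed integer seed.
#' @param target_name name of the admixed target population.
#' @param terminal_drift Balding-Nichols drift on the target after mixing.
#' @param pseudo_haploid sample one allele per source individual instead
#'   of two (robustness switch emulating pseudo-haploid genotype calls of
#'   ancient samples).
#' @return list with `fp` (a `freq_panel` containing target, sources and
#'   outgroups), `sources`, `outgroups`, and `ledger` (truth alphas,
#'   seed, drift settings).
#' @export
make_qpadm_fixture <- function(n_sites = 1e5, alphas = default_threeway_alphas(),
                               seed = 1, target_name = "Target_TB",
                               terminal_drift = 0.01, roles = NULL,
                               pseudo_haploid = FALSE) {
  if (abs(sum(alphas) - 1) > 1e-8) abort("alphas must sum to 1")
  if (is.null(names(alphas))) abort("alphas must be named by source")
  sources <- names(alphas)
  outgroups <- c("Mbuti", "GanjDareh_N", "Villabruna_HG", "Mixe", "Papuan",
                 "Onge", "Atayal")
  # continental scaffold: the outgroups must be differentially related to
  # the source lineages, otherwise the f4 system carries no weight signal
  scaffold <- dplyr::tribble(
    ~name,           ~parent,     ~f,
    "root",          NA,          0,
    "Mbuti",         "root",      0.40,
    "eurasia",       "root",      0.05,
    "west",          "eurasia",   0.05,
    "GanjDareh_N",   "west",      0.10,
    "Villabruna_HG", "west",      0.12,
    "east",          "eurasia",   0.04,
    "Papuan",        "east",      0.25,
    "Onge",          "east",      0.15,
    "eastasia",      "east",      0.04,
    "Mixe",          "eastasia",  0.20,
    "NEasia",        "eastasia",  0.03,
    "SEasia",        "eastasia",  0.03,
    "Atayal",        "SEasia",    0.08)
  default_roles <- c(Lajia_LN = "NEasia", Miaozigou_MN = "NEasia",
                     Boshan_EN = "NEasia", Pingliangtai_LN = "NEasia",
                     Taiwan_Hanben = "SEasia", Ami = "SEasia",
                     Russia_Sarmatian = "west", Hoabinhian = "east")
  if (is.null(roles)) roles <- default_roles[sources]
  if (anyNA(roles))
    abort(paste("no scaffold role for source(s):",
                paste(sources[is.na(roles)], collapse = ", "),
                "- pass `roles` explicitly"))
  anc <- paste0(sources, "_anc")
  nodes <- bind_rows(
    scaffold,
    tibble(name = anc, parent = unname(roles), f = 0.03),
    tibble(name = sources, parent = anc, f = 0.04))
  nodes$mix <- vector("list", nrow(nodes))
  target <- tibble(name = target_name, parent = NA_character_,
                   f = terminal_drift,
                   mix = list(setNames(as.numeric(alphas), anc)))
  nodes <- bind_rows(nodes, target)
  n_src <- if (pseudo_haploid) 5L else 10L
  sample_n <- c(setNames(rep(40L, length(outgroups)), outgroups),
                setNames(rep(n_src, length(sources)), sources),
                setNames(40L, target_name))
  fp <- simulate_freq_panel(nodes, n_sites = n_sites, sample_n = sample_n,
                            seed = derive_seed(seed, 71))
  ledger <- list(alphas = as.list(alphas), seed = seed,
                 terminal_drift = terminal_drift, n_sites = n_sites,
                 target = target_name, sources = sources,
                 outgroups = outgroups, roles = as.list(roles),
                 pseudo_haploid = pseudo_haploid)
  list(fp = fp, target = target_name, sources = sources,
       outgroups = outgroups, ledger = ledger)
}
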