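#' Built-in demographic scenarios for Sino-Tibetan population history
#'
#' Six competing models of the divergence of Tibetan, other Tibeto-Burman
#' and Han Chinese populations, in two tiers.  The base tier uses four
#' populations (Northern Han, Southern Han, Muli Tibetan, Lhasa Tibetan) and
#' contrasts (i) a common origin of the geographically separated Tibetan
#' groups, (ii) an early split where the lowland (Muli) Tibetans are sister
#' to the Han clade, and (iii) a hybrid origin like (ii) but with continuous
#' gene flow from highland into lowland Tibetans.  The extended tier uses
#' six populations (adding Dujiangyan Tibetan, Xichang Yi and Yanyuan Mosuo,
#' keeping a single Han lineage) and contrasts whether the Yi/Mosuo pair
#' shares its ancestry with the Tibetan clade, with the Han lineage, or with
#' Muli Tibetan specifically.
#'
#' Split-time defaults are the study system's point estimates (Han vs
#' Tibeto-Burman ~9.9 kya; Tibetan vs non-Tibetan Tibeto-Burman ~4.2 kya;
#' Muli vs highland Tibetan ~3.4 kya; Yi vs Mosuo ~2.2 kya; Dujiangyan vs
#' Lhasa ~1.2 kya; generation time 29 y).  Quantities without published
#' point estimates use documented defaults: Han lineages at diploid N_e
#' 20,000, Tibeto-Burman lineages and their internal branches at 5,000
#' (these groups maintained small effective sizes), deep ancestral
#' branches at 10,000; a bottleneck of N_e 1,000 lasting 10 generations on
#' the ancestral Tibeto-Burman branch immediately older than its basal
#' split (carried by the common-origin topologies); symmetric continuous
#' migration 1e-4 per generation on within-clade contact edges;
#' Northern-Southern Han split 6.0 kya.
#'
#' Backward in time, a derived population's lineages join the deme of its
#' sister/ancestral population, so ancestral branches are carried by an
#' existing deme (the one named in `ancestral`).
#'
#' @param name one of `"base_common_origin"`, `"base_early_split"`,
#'   `"base_hybrid_origin"`, `"ext_tb_with_tibetan"`, `"ext_tb_with_han"`,
#'   `"ext_tb_with_muli"`.
#' @param gen_time generation time in years.
#' @return a list with elements `model` (a [demog_model()] whose split times
#'   are free parameters), `space` (tibble of free parameters with `name`,
#'   `min`, `max`, `scale` columns, ranges in generations), `constraints`
#'   (tibble of `lower`/`upper` parameter pairs: `lower` must stay below
#'   `upper` during optimization) and `truth` (named vector of generating
#'   split times in generations).
#' @export
scenario_library <- function(name, gen_time = 29) {
  valid <- c("base_common_origin", "base_early_split", "base_hybrid_origin",
             "ext_tb_with_tibetan", "ext_tb_with_han", "ext_tb_with_muli")
  if (!name %in% valid)
    abort(paste0("unknown scenario '", name, "'; valid names: ",
                 paste(valid, collapse = ", ")))
  kya <- function(x) years_to_generations(x * 1000, gen_time)
  # documented defaults for unprinted parameters: Han lineages are large
  # (N_e 20,000), Tibeto-Burman lineages and their internal branches small
  # (N_e 5,000, matching the study system's reported small TB sizes), deep
  # ancestral branches 10,000; bottleneck N_e 1,000 for 10 generations
  NE_HAN <- 2e4; NE_TB <- 5e3; NE_ANC <- 1e4; NB <- 1e3; BOT <- 10
  MIG <- 1e-4
  sp <- function(name, min, max)
    tibble(name = name, min = min, max = max, scale = "log")
  bottleneck <- function(pop, t)
    tibble(pop = pop, t_start = t, t_end = paste0(t, "+", BOT), size = NB)
  sym_mig <- function(a, b, t_end, rate = MIG)
    tibble(from = c(a, b), to = c(b, a), rate = rate, t_start = 0,
           t_end = t_end)

  if (startsWith(name, "base")) {
    pops <- tibble(name = c("NorthernHan", "SouthernHan", "MuliTibetan",
                            "LhasaTibetan"),
                   size = c(NE_HAN, NE_HAN, NE_TB, NE_TB))
    truth <- c(T_han = kya(6.0), T_tib = kya(3.4), T_deep = kya(9.9))
    space <- dplyr::bind_rows(sp("T_deep", 120, 650), sp("T_han", 60, 330),
                              sp("T_tib", 20, 260))
    constraints <- tibble(lower = c("T_han", "T_tib"),
                          upper = c("T_deep", "T_deep"))
    migrations <- sym_mig("NorthernHan", "SouthernHan", "T_han")
    size_changes <- NULL
    if (name == "base_common_origin") {
      splits <- tibble(
        time = c("T_han", "T_tib", "T_deep"),
        derived = c("SouthernHan", "MuliTibetan", "LhasaTibetan"),
        ancestral = c("NorthernHan", "LhasaTibetan", "NorthernHan"),
        size = c(NE_HAN, NE_TB, NE_ANC))
      migrations <- dplyr::bind_rows(
        migrations, sym_mig("MuliTibetan", "LhasaTibetan", "T_tib"))
      size_changes <- bottleneck("LhasaTibetan", "T_tib")
    } else {
      # Muli sister to the Han clade; highland (Lhasa) Tibetans split deepest
      splits <- tibble(
        time = c("T_han", "T_tib", "T_deep"),
        derived = c("SouthernHan", "MuliTibetan", "LhasaTibetan"),
        ancestral = c("NorthernHan", "NorthernHan", "NorthernHan"),
        size = c(NE_HAN, NE_HAN, NE_ANC))
      if (name == "base_hybrid_origin") {
        # forward gene flow highland -> lowland Tibetans: backward, Muli
        # lineages trace into the Lhasa deme
        migrations <- dplyr::bind_rows(migrations, tibble(
          from = "MuliTibetan", to = "LhasaTibetan", rate = 5 * MIG,
          t_start = 0, t_end = "T_tib"))
      }
    }
  } else {
    pops <- tibble(name = c("NorthernHan", "LhasaTibetan", "DujiangyanTibetan",
                            "MuliTibetan", "XichangYi", "YanyuanMosuo"),
                   size = c(NE_HAN, rep(NE_TB, 5)))
    truth <- c(T_djy = kya(1.2), T_ym = kya(2.2), T_muli = kya(3.4),
               T_tibnon = kya(4.2), T_deep = kya(9.9))
    space <- dplyr::bind_rows(
      sp("T_deep", 150, 650), sp("T_tibnon", 50, 280), sp("T_muli", 15, 180),
      sp("T_ym", 5, 160), sp("T_djy", 5, 120))
    migrations <- sym_mig("MuliTibetan", "LhasaTibetan", "T_muli")
    size_changes <- NULL
    if (name == "ext_tb_with_tibetan") {
      # best-fit topology: ((Lhasa,DJY),Muli) Tibetan clade joined by the
      # (Yi,Mosuo) clade at T_tibnon, bottleneck on the TB ancestor
      splits <- tibble(
        time = c("T_djy", "T_muli", "T_ym", "T_tibnon", "T_deep"),
        derived = c("DujiangyanTibetan", "MuliTibetan", "YanyuanMosuo",
                    "XichangYi", "LhasaTibetan"),
        ancestral = c("LhasaTibetan", "LhasaTibetan", "XichangYi",
                      "LhasaTibetan", "NorthernHan"),
        size = c(NE_TB, NE_TB, NE_TB, NE_TB, NE_ANC))
      constraints <- tibble(
        lower = c("T_djy", "T_muli", "T_ym", "T_tibnon"),
        upper = c("T_muli", "T_tibnon", "T_tibnon", "T_deep"))
      size_changes <- bottleneck("LhasaTibetan", "T_tibnon")
    } else if (name == "ext_tb_with_han") {
      # Yi/Mosuo share ancestry with the Han lineage
      splits <- tibble(
        time = c("T_djy", "T_muli", "T_ym", "T_tibnon", "T_deep"),
        derived = c("DujiangyanTibetan", "MuliTibetan", "YanyuanMosuo",
                    "XichangYi", "LhasaTibetan"),
        ancestral = c("LhasaTibetan", "LhasaTibetan", "XichangYi",
                      "NorthernHan", "NorthernHan"),
        size = c(NE_TB, NE_TB, NE_TB, NE_ANC, NE_ANC))
      constraints <- tibble(
        lower = c("T_djy", "T_muli", "T_ym", "T_tibnon"),
        upper = c("T_muli", "T_deep", "T_tibnon", "T_deep"))
    } else {
      # Yi/Mosuo share ancestry with Muli Tibetan
      splits <- tibble(
        time = c("T_djy", "T_ym", "T_muli", "T_tibnon", "T_deep"),
        derived = c("DujiangyanTibetan", "YanyuanMosuo", "XichangYi",
                    "MuliTibetan", "LhasaTibetan"),
        ancestral = c("LhasaTibetan", "XichangYi", "MuliTibetan",
                      "LhasaTibetan", "NorthernHan"),
        size = c(NE_TB, NE_TB, NE_TB, NE_TB, NE_ANC))
      constraints <- tibble(
        lower = c("T_djy", "T_ym", "T_muli", "T_tibnon"),
        upper = c("T_tibnon", "T_muli", "T_tibnon", "T_deep"))
    }
  }
  model <- demog_model(populations = pops, splits = splits,
                       size_changes = size_changes, migrations = migrations,
                       gen_time = gen_time)
  list(model = model, space = space, constraints = constraints, truth = truth)
}
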