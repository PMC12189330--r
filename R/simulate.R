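#' Configuration for the structured pedigree generator
#'
#' Defines the study conditions the generator emulates: several regional
#' nuclei with their own founder pools, limited sire migration between
#' regions (the demographic footprint of transhumance), a controllable
#' propensity for matings between close relatives (deliberate inbreeding
#' loops), and masked parentage in the earliest recorded generation.
#'
#' @param n_regions number of regions (provinces), >= 1.
#' @param founders_per_region founders in each regional pool (sexes
#'   alternate, so pools are always mateable).
#' @param n_generations discrete non-overlapping generations after the
#'   founders.
#' @param matings_per_region matings per region and generation.
#' @param offspring_per_mating offspring per mating; with the default 2 each
#'   mating leaves one male and one female, so full sibs are always available
#'   to the loop policy.
#' @param migration_rate per-generation probability that a dam is mated to an
#'   out-of-region sire; scalar or length `n_regions`.
#' @param loop_intensity probability that a mating deliberately pairs
#'   relatives (full sibs preferred, then half sibs); scalar or per-region.
#' @param unknown_parent_rate probability that each parent link of a
#'   first-generation animal is masked (incomplete early records).
#' @param munis_per_region municipalities nested within each region.
#' @param base_year first birth year.
#' @param seed mandatory integer seed; the same seed reproduces the pedigree
#'   byte for byte.
#' @return a `sim_config` list (validated).
#' @export
sim_config <- function(n_regions = 3, founders_per_region = 12,
                       n_generations = 6, matings_per_region = 12,
                       offspring_per_mating = 2, migration_rate = 0.1,
                       loop_intensity = 0.1, unknown_parent_rate = 0.2,
                       munis_per_region = 3, base_year = 1994, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  cfg <- list(n_regions = as.integer(n_regions),
              founders_per_region = as.integer(founders_per_region),
              n_generations = as.integer(n_generations),
              matings_per_region = as.integer(matings_per_region),
              offspring_per_mating = as.integer(offspring_per_mating),
              migration_rate = rep_len(migration_rate, n_regions),
              loop_intensity = rep_len(loop_intensity, n_regions),
              unknown_parent_rate = unknown_parent_rate,
              munis_per_region = as.integer(munis_per_region),
              base_year = as.integer(base_year),
              seed = as.integer(seed))
  stopifnot(cfg$n_regions >= 1, cfg$founders_per_region >= 2,
            cfg$n_generations >= 1, cfg$matings_per_region >= 1,
            cfg$offspring_per_mating >= 1,
            all(cfg$migration_rate >= 0 & cfg$migration_rate <= 1),
            all(cfg$loop_intensity >= 0 & cfg$loop_intensity <= 1),
            cfg$unknown_parent_rate >= 0, cfg$unknown_parent_rate <= 1)
  class(cfg) <- "sim_config"
  cfg
}

# run expr with the RNG seeded, restoring the caller's RNG state afterwards
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.pick1 <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

#' Generate a regionally structured pedigree
#'
#' Builds a pedigree with discrete non-overlapping generations: each region
#' starts from its own founder pool and each mating draws a dam from the
#' region's previous generation. The sire is, in order of precedence, a close
#' relative of the dam (with probability `loop_intensity`; full brother
#' preferred, then half brother), an out-of-region male (with probability
#' `migration_rate`), or a random male of the region. Offspring inherit the
#' dam's municipality; sexes alternate within a mating. Parent links of
#' first-generation animals are masked with probability
#' `unknown_parent_rate`, and the last two generations are flagged alive.
#'
#' @param config a [sim_config()].
#' @return a `pedigree` with province ("R1", "R2", ...) and municipality
#'   ("R1M1", ...) labels and a `generation` attribute.
#' @export
generate_structured_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  .with_seed(cfg$seed, {
    rec <- list()
    mk <- function(id, sire, dam, sex, gen, region, muni, year, doy) {
      list(id = id, sire = as.character(sire), dam = as.character(dam),
           sex = sex, gen = gen, region = region, municipality = muni,
           birth_date = sprintf("%04d-%02d-%02d", year, 1 + (doy %/% 28) %% 12,
                                1 + doy %% 28))
    }
    for (r in seq_len(cfg$n_regions)) {
      for (k in seq_len(cfg$founders_per_region)) {
        rec[[length(rec) + 1L]] <- mk(
          sprintf("R%dG0N%03d", r, k), NA, NA,
          if (k %% 2L == 1L) "male" else "female", 0L, r,
          sprintf("R%dM%d", r, 1L + (k - 1L) %% cfg$munis_per_region),
          cfg$base_year, k)
      }
    }
    df <- function(lst) data.frame(id = vapply(lst, `[[`, "", "id"),
                                   sex = vapply(lst, `[[`, "", "sex"),
                                   gen = vapply(lst, `[[`, 0L, "gen"),
                                   region = vapply(lst, `[[`, 0L, "region"),
                                   sire = vapply(lst, `[[`, NA_character_, "sire"),
                                   dam = vapply(lst, `[[`, NA_character_, "dam"),
                                   stringsAsFactors = FALSE)

    for (g in seq_len(cfg$n_generations)) {
      prev <- df(rec)
      prev <- prev[prev$gen == g - 1L, , drop = FALSE]
      for (r in seq_len(cfg$n_regions)) {
        pr <- prev[prev$region == r, , drop = FALSE]
        dams_pool <- pr$id[pr$sex == "female"]
        sires_pool <- pr$id[pr$sex == "male"]
        if (!length(dams_pool) || !length(sires_pool))
          stop("infeasible configuration: no ", if (length(dams_pool)) "males" else "females",
               " in region R", r, " at generation ", g)
        out_sires <- prev$id[prev$sex == "male" & prev$region != r]
        cnt <- 0L
        for (mt in seq_len(cfg$matings_per_region)) {
          dam <- .pick1(dams_pool)
          drow <- pr[pr$id == dam, ]
          sire <- NULL
          if (stats::runif(1) < cfg$loop_intensity[r]) {
            full <- pr$id[pr$sex == "male" & !is.na(pr$sire) & !is.na(pr$dam) &
                          pr$sire %in% drow$sire & pr$dam %in% drow$dam]
            half <- pr$id[pr$sex == "male" &
                          ((!is.na(pr$sire) & pr$sire %in% drow$sire) |
                           (!is.na(pr$dam) & pr$dam %in% drow$dam))]
            half <- setdiff(half, full)
            if (length(full)) sire <- .pick1(full)
            else if (length(half)) sire <- .pick1(half)
          }
          if (is.null(sire) && length(out_sires) &&
              stats::runif(1) < cfg$migration_rate[r]) {
            sire <- .pick1(out_sires)
          }
          if (is.null(sire)) sire <- .pick1(sires_pool)
          dmuni <- rec[[which(vapply(rec, `[[`, "", "id") == dam)]]$municipality
          for (o in seq_len(cfg$offspring_per_mating)) {
            cnt <- cnt + 1L
            rec[[length(rec) + 1L]] <- mk(
              sprintf("R%dG%dN%03d", r, g, cnt), sire, dam,
              if (o %% 2L == 1L) "male" else "female", g, r, dmuni,
              cfg$base_year + 2L * g, cnt)
          }
        }
      }
    }

    all <- df(rec)
    gen <- all$gen
    sire <- all$sire; dam <- all$dam
    mask <- gen == 1L
    if (any(mask) && cfg$unknown_parent_rate > 0) {
      ms <- mask & stats::runif(length(mask)) < cfg$unknown_parent_rate
      md <- mask & stats::runif(length(mask)) < cfg$unknown_parent_rate
      sire[ms] <- NA; dam[md] <- NA
    }
    ped <- as_pedigree(data.frame(
      id = all$id, sire = sire, dam = dam, sex = all$sex,
      birth_date = vapply(rec, `[[`, "", "birth_date"),
      municipality = vapply(rec, `[[`, "", "municipality"),
      province = sprintf("R%d", all$region),
      alive = gen >= cfg$n_generations - 1L,
      stringsAsFactors = FALSE))
    attr(ped, "generation") <- stats::setNames(gen, all$id)[ped$id]
    attr(ped, "config") <- cfg
    ped
  })
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || (length(a) == 1 && is.na(a))) b else a

# ancestors reachable in exactly `depth` parent steps
.anc_at_depth <- function(ped, pos, depth) {
  cur <- pos
  for (k in seq_len(depth)) {
    cur <- unique(c(ped$sire_i[cur], ped$dam_i[cur]))
    cur <- cur[cur > 0L]
    if (!length(cur)) return(integer(0))
  }
  cur
}

#' Inject inbreeding loops into a pedigree
#'
#' Appends `count` matings within a focal region whose sire and dam share an
#' ancestor exactly `depth` generations back, so the shared ancestors become
#' nodal common ancestors of the new offspring by construction.
#'
#' @param ped pedigree (province labels required).
#' @param focal_region province label to operate in.
#' @param depth generations back to the shared ancestor (1 = sibs).
#' @param count number of matings to add (0 returns the pedigree unchanged).
#' @param seed integer seed.
#' @return the augmented `pedigree`; new animals are labeled
#'   "LOOP<depth>_<k>" and carry the focal region's labels.
#' @export
inject_inbreeding_loops <- function(ped, focal_region, depth, count, seed) {
  stopifnot(inherits(ped, "pedigree"), depth >= 1, count >= 0)
  if (count == 0) return(ped)
  if (!focal_region %in% ped$province) stop("unknown region: ", focal_region)
  .with_seed(seed, {
    in_reg <- which(ped$province %in% focal_region)
    males <- in_reg[ped$sex[in_reg] == "male"]
    females <- in_reg[ped$sex[in_reg] == "female"]
    anc_m <- lapply(males, function(p) .anc_at_depth(ped, p, depth))
    anc_f <- lapply(females, function(p) .anc_at_depth(ped, p, depth))
    pairs <- list()
    for (i in seq_along(males)) for (j in seq_along(females)) {
      if (length(intersect(anc_m[[i]], anc_f[[j]])))
        pairs[[length(pairs) + 1L]] <- c(males[i], females[j])
    }
    if (!length(pairs)) stop("no eligible pairs sharing an ancestor at depth ", depth)
    take <- if (count > length(pairs)) sample.int(length(pairs), count, replace = TRUE)
            else sample.int(length(pairs), count)
    last_date <- if (all(is.na(ped$birth_date))) as.Date("2000-01-01")
                 else max(ped$birth_date, na.rm = TRUE)
    add <- do.call(rbind, lapply(seq_along(take), function(k) {
      pr <- pairs[[take[k]]]
      data.frame(id = sprintf("LOOP%d_%d", depth, k),
                 sire = ped$id[pr[1L]], dam = ped$id[pr[2L]],
                 sex = if (k %% 2L) "male" else "female",
                 birth_date = format(last_date + 365, "%Y-%m-%d"),
                 municipality = ped$municipality[pr[2L]],
                 province = focal_region, alive = TRUE,
                 stringsAsFactors = FALSE)
    }))
    old <- as.data.frame(ped)[, c("id", "sire", "dam", "sex", "birth_date",
                                  "municipality", "province", "alive")]
    old$birth_date <- format(old$birth_date, "%Y-%m-%d")
    as_pedigree(rbind(old, add))
  })
}

#' Reference fixture pedigrees
#'
#' Four tiny pedigrees with textbook closed forms, used throughout the test
#' suite and documentation:
#' \describe{
#'   \item{FIX-FS}{full-sib mating: founders A, B; S = A x B; D = A x B;
#'     X = S x D; F_X = 0.25, NCAs \{A, B\}.}
#'   \item{FIX-HS}{paternal half-sib mating: founders A, B, C; S = A x B;
#'     D = A x C; X = S x D; F_X = 0.125, NCA \{A\}.}
#'   \item{FIX-PO}{sire-daughter mating: founders A, B; D = A x B; X = A x D;
#'     F_X = 0.25, NCA \{A\}.}
#'   \item{FIX-CHAIN}{founders A, B, C, E; M = A x B; S = M x C; D = M x E;
#'     X = S x D; F_X = 0.125, marginal NCA contribution concentrated in M.}
#' }
#'
#' @return named list of `pedigree` objects.
#' @export
reference_fixtures <- function() {
  list(
    "FIX-FS" = as_pedigree(data.frame(
      id = c("A", "B", "S", "D", "X"), sire = c("0", "0", "A", "A", "S"),
      dam = c("0", "0", "B", "B", "D"),
      sex = c("male", "female", "male", "female", "male"))),
    "FIX-HS" = as_pedigree(data.frame(
      id = c("A", "B", "C", "S", "D", "X"), sire = c("0", "0", "0", "A", "A", "S"),
      dam = c("0", "0", "0", "B", "C", "D"),
      sex = c("male", "female", "female", "male", "female", "male"))),
    "FIX-PO" = as_pedigree(data.frame(
      id = c("A", "B", "D", "X"), sire = c("0", "0", "A", "A"),
      dam = c("0", "0", "B", "D"),
      sex = c("male", "female", "female", "male"))),
    "FIX-CHAIN" = as_pedigree(data.frame(
      id = c("A", "B", "C", "E", "M", "S", "D", "X"),
      sire = c("0", "0", "0", "0", "A", "M", "M", "S"),
      dam = c("0", "0", "0", "0", "B", "C", "E", "D"),
      sex = c("male", "female", "female", "female", "male", "male", "female", "male")))
  )
}
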