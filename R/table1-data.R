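# Published 2x2 (and 2xL) anemic / non-anemic counts by categorical
# covariate from the 2014/2015 Rwanda DHS childhood anemia survey table.
# Counts are authoritative; a handful of the survey's printed row
# percentages are not consistent with these counts (they embed complex
# survey weighting) and are not reproduced here.
table1_counts <- list(
  sex = list(levels = c("male", "female"),
             anemic = c(607, 583), non_anemic = c(1038, 1020)),
  birth_order = list(levels = c("1st", "2-3", "4-5", "6+"),
                     anemic = c(330, 458, 230, 172),
                     non_anemic = c(830, 595, 273, 361)),
  ate_meat_fish = list(levels = c("yes", "no"),
                       anemic = c(35, 736), non_anemic = c(31, 987)),
  fever = list(levels = c("yes", "no"),
               anemic = c(298, 892), non_anemic = c(373, 1685)),
  cough = list(levels = c("yes", "no"),
               anemic = c(372, 818), non_anemic = c(581, 1477)),
  diarrhea = list(levels = c("no", "yes"),
                  anemic = c(993, 197), non_anemic = c(1816, 242)),
  stunted = list(levels = c("no", "yes"),
                 anemic = c(740, 451), non_anemic = c(1388, 670)),
  underweight = list(levels = c("no", "yes"),
                     anemic = c(1157, 34), non_anemic = c(2034, 24)),
  wasting = list(levels = c("no", "yes"),
                 anemic = c(992, 199), non_anemic = c(1838, 220)),
  birth_weight = list(levels = c("low", "higher"),
                      anemic = c(57, 1039), non_anemic = c(92, 1817)),
  vitamin_a = list(levels = c("yes", "no"),
                   anemic = c(1005, 185), non_anemic = c(1840, 218)),
  deworming = list(levels = c("yes", "no"),
                   anemic = c(873, 317), non_anemic = c(1766, 292)),
  mother_education = list(levels = c("none", "primary", "secondary", "higher"),
                          anemic = c(189, 857, 126, 18),
                          non_anemic = c(289, 1523, 199, 48)),
  mother_anemia = list(levels = c("anemic", "not_anemic"),
                       anemic = c(279, 912), non_anemic = c(305, 1753)),
  mother_literacy = list(levels = c("yes", "no"),
                         anemic = c(877, 313), non_anemic = c(1594, 464)),
  household_size = list(levels = c("1-3", "4+"),
                        anemic = c(203, 987), non_anemic = c(323, 1735)),
  residence = list(levels = c("urban", "rural"),
                   anemic = c(156, 1034), non_anemic = c(364, 1694)),
  wealth = list(levels = c("poor", "middle", "rich"),
                anemic = c(617, 240, 333), non_anemic = c(910, 408, 740)),
  mother_bmi = list(levels = c("under_18.5", "18.5_plus"),
                    anemic = c(58, 1133), non_anemic = c(85, 1973)),
  mosquito_net = list(levels = c("yes", "no"),
                      anemic = c(1007, 183), non_anemic = c(1770, 288)),
  household_head = list(levels = c("female", "male"),
                        anemic = c(235, 956), non_anemic = c(375, 1683))
)

#' Survey cross-tabulation fixture
#'
#' Reconstructs a child-level categorical dataset whose per-variable
#' cross-tabulations against the anemic / non-anemic outcome reproduce the
#' published survey counts exactly.  Only the 2-way margins of each variable
#' with anemia status are published, so variables are laid out independently
#' of each other: within the anemic and non-anemic row blocks each variable
#' fills its own printed cell counts and is `NA` on any remaining rows
#' (variable totals differ slightly across the published table).
#'
#' @return a data.frame with an `anemic` factor (`"yes"`/`"no"`) and one
#'   factor column per published categorical covariate.  [anemia_crosstab()]
#'   on any column reproduces that variable's printed counts.
#' @examples
#' fx <- table1_fixture()
#' anemia_crosstab(fx, "sex")$counts  # 607/1038 male, 583/1020 female
#' @export
table1_fixture <- function() {
  n_anemic <- max(vapply(table1_counts, function(v) sum(v$anemic), 0))
  n_non <- max(vapply(table1_counts, function(v) sum(v$non_anemic), 0))
  out <- data.frame(anemic = factor(rep(c("yes", "no"), c(n_anemic, n_non)),
                                    levels = c("yes", "no")))
  fill_block <- function(counts, levels, n_block) {
    v <- rep(NA_character_, n_block)
    v[seq_len(sum(counts))] <- rep(levels, counts)
    v
  }
  for (nm in names(table1_counts)) {
    spec <- table1_counts[[nm]]
    out[[nm]] <- factor(c(fill_block(spec$anemic, spec$levels, n_anemic),
                          fill_block(spec$non_anemic, spec$levels, n_non)),
                        levels = spec$levels)
  }
  out
}
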