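#' Questionnaire vocabularies and numeric mappings
#'
#' The food-frequency instrument asks about each meat/fish/cheese item on a
#' six-level frequency scale, about fruit in pieces/day, vegetables in
#' tablespoons/day, coffee and tea in cups/day, milk by type plus the number
#' of cereal bowls and milky drinks, and alcohol on a six-level frequency
#' scale.  "Do not know" / "prefer not to answer" are treated as missing
#' upstream of this module (factor level `"missing"` or NA).
#'
#' `diet_options()` collects the numeric constants: frequency-category
#' midpoints (times/week), tablespoons per vegetable serving, and millilitres
#' of milk per cereal bowl / per milky drink.
#'
#' @param freq_midpoints named numeric, one value per frequency level.
#' @param tbsp_per_serving tablespoons of vegetables per serving (default 3).
#' @param milk_per_bowl_ml,milk_per_drink_ml millilitres of milk per bowl of
#'   cereal and per cup of tea/coffee taken with milk.
#' @return list of constants used by [derive_food_groups()].
#' @export
diet_options <- function(freq_midpoints = c(never = 0, less_than_once_week = 0.5,
                                            once_week = 1, two_to_four_week = 3,
                                            five_to_six_week = 5.5,
                                            daily_or_more = 7),
                         tbsp_per_serving = 3,
                         milk_per_bowl_ml = 125,
                         milk_per_drink_ml = 30) {
  stopifnot(all(freq_midpoints >= 0), tbsp_per_serving > 0)
  list(freq_midpoints = freq_midpoints,
       tbsp_per_serving = tbsp_per_serving,
       milk_per_bowl_ml = milk_per_bowl_ml,
       milk_per_drink_ml = milk_per_drink_ml)
}

freq_levels <- c("never", "less_than_once_week", "once_week",
                 "two_to_four_week", "five_to_six_week", "daily_or_more")
alcohol_levels <- c("never", "special_occasions", "one_to_three_monthly",
                    "once_or_twice_week", "three_or_four_week",
                    "daily_or_almost_daily")
milk_types <- c("none", "full_cream", "semi_skimmed", "skimmed")

## map a frequency factor to weekly midpoints; unknown token -> error
freq_to_weekly <- function(x, item, midpoints) {
  ch <- as.character(x)
  ch[ch %in% "missing"] <- NA
  bad <- !is.na(ch) & !(ch %in% names(midpoints))
  if (any(bad)) {
    stop("unknown frequency category for item '", item, "': ",
         paste(unique(ch[bad]), collapse = ", "))
  }
  unname(midpoints[ch])
}

#' Derive food groups from raw questionnaire answers
#'
#' Aggregates single questionnaire items into the eleven analysed food
#' groups: red meat = beef + lamb/mutton + pork (times/week, each frequency
#' category mapped to its numeric midpoint); total fish = oily + non-oily
#' fish; total fruit = fresh + dried (servings/day); total vegetables =
#' (cooked + salad/raw tablespoons) / tablespoons-per-serving; daily milk
#' volume from milk type, cereal bowls and milky drinks; processed meat,
#' poultry, cheese, coffee, tea and the six-level alcohol frequency pass
#' through.  A group with any missing constituent answer is missing.
#'
#' @param cohort data.frame with the raw item columns (see
#'   [simulate_cohort()] for the schema).
#' @param opts constants from [diet_options()].
#' @return data.frame of per-participant group quantities plus, for each
#'   group, its analysis category (`*_cat`, reference level first); see
#'   [diet_cutpoints()].
#' @export
derive_food_groups <- function(cohort, opts = diet_options()) {
  mp <- opts$freq_midpoints
  w <- function(col) freq_to_weekly(cohort[[col]], col, mp)
  red_meat <- w("beef_freq") + w("lamb_freq") + w("pork_freq")
  processed_meat <- w("processed_meat_freq")
  poultry <- w("poultry_freq")
  total_fish <- w("oily_fish_freq") + w("nonoily_fish_freq")
  cheese <- w("cheese_freq")
  total_fruit <- cohort$fresh_fruit_pieces + cohort$dried_fruit_pieces
  total_veg <- (cohort$cooked_veg_tbsp + cohort$salad_veg_tbsp) / opts$tbsp_per_serving
  mt <- as.character(cohort$milk_type)
  mt[mt %in% "missing"] <- NA
  bad <- !is.na(mt) & !(mt %in% milk_types)
  if (any(bad)) stop("unknown milk type: ", paste(unique(mt[bad]), collapse = ", "))
  milk <- ifelse(mt == "none", 0,
                 cohort$cereal_bowls * opts$milk_per_bowl_ml +
                   (cohort$coffee_cups + cohort$tea_cups) * opts$milk_per_drink_ml)
  milk[is.na(mt)] <- NA
  alcohol <- as.character(cohort$alcohol_freq)
  alcohol[alcohol %in% "missing"] <- NA
  bad <- !is.na(alcohol) & !(alcohol %in% alcohol_levels)
  if (any(bad)) stop("unknown alcohol category: ", paste(unique(alcohol[bad]), collapse = ", "))
  out <- data.frame(
    red_meat = red_meat, processed_meat = processed_meat, poultry = poultry,
    total_fish = total_fish, milk = milk, cheese = cheese,
    total_fruit = total_fruit, total_veg = total_veg,
    coffee = cohort$coffee_cups, tea = cohort$tea_cups,
    alcohol = factor(alcohol, levels = alcohol_levels)
  )
  cbind(out, assign_diet_categories(out))
}

#' Analysis categories for the eleven food groups
#'
#' Returns the category scheme used throughout the risk models: label set,
#' break points and closure side per food.  The first label of each food is
#' the reference category.
#' @return named list of per-food definitions.
#' @export
diet_cutpoints <- function() {
  list(
    red_meat = list(breaks = c(2, 3), right = FALSE,
                    labels = c("<2", "2 to <3", ">=3")),
    processed_meat = list(breaks = c(1, 2), right = FALSE,
                          labels = c("<1", "1", ">=2")),
    poultry = list(breaks = c(1, 2), right = FALSE,
                   labels = c("<1", "1", ">=2")),
    total_fish = list(breaks = c(1, 2), right = TRUE,
                      labels = c("<=1", ">1 to <=2", ">2")),
    milk = list(breaks = c(200, 300), right = FALSE,
                labels = c("<200", "200 to <300", ">=300")),
    cheese = list(breaks = c(2, 5), right = FALSE,
                  labels = c("<2", "2 to 4", ">=5")),
    total_fruit = list(breaks = c(2, 4), right = FALSE,
                       labels = c("<2", "2 to <4", ">=4")),
    total_veg = list(breaks = c(4, 6), right = FALSE,
                     labels = c("<4", "4 to <6", ">=6")),
    coffee = list(breaks = c(0, 2), right = TRUE,
                  labels = c("<1", "1 to <=2", ">2")),
    tea = list(breaks = c(3, 5), right = FALSE,
               labels = c("<3", "3 to <5", ">=5")),
    alcohol = list(labels = c("<1", "1 to 2", ">=3"))
  )
}

## alcohol six-level questionnaire item -> three weekly-frequency categories
alcohol_to_weekly_cat <- function(alcohol) {
  map <- c(never = "<1", special_occasions = "<1", one_to_three_monthly = "<1",
           once_or_twice_week = "1 to 2", three_or_four_week = ">=3",
           daily_or_almost_daily = ">=3")
  factor(unname(map[as.character(alcohol)]), levels = c("<1", "1 to 2", ">=3"))
}

assign_diet_categories <- function(groups) {
  cp <- diet_cutpoints()
  out <- data.frame(row.names = seq_len(nrow(groups)))
  for (food in setdiff(names(cp), "alcohol")) {
    def <- cp[[food]]
    idx <- .bincode(groups[[food]], breaks = c(-Inf, def$breaks, Inf),
                    right = def$right)
    out[[paste0(food, "_cat")]] <- factor(def$labels[idx], levels = def$labels)
  }
  out$alcohol_cat <- alcohol_to_weekly_cat(groups$alcohol)
  out
}

#' WCRF dietary adherence score
#'
#' Counts adherence to three WCRF/AICR dietary recommendations: (1) red plus
#' processed meat under 4 times/week; (2) fruit plus vegetables over 5
#' servings/day; (3) alcohol under 3 times/month (questionnaire levels never,
#' special occasions only, or one-to-three times a month).  Participants with
#' any required group missing get NA (complete-case).
#'
#' @param groups data.frame from [derive_food_groups()].
#' @return data.frame with logical component flags `wcrf_meat`,
#'   `wcrf_fruit_veg`, `wcrf_alcohol`, the integer `wcrf_score` (0-3) and the
#'   dichotomised `wcrf_group` factor ("2-3" = healthier, reference; "0-1").
#' @export
wcrf_score <- function(groups) {
  meat <- (groups$red_meat + groups$processed_meat) < 4
  fv <- (groups$total_fruit + groups$total_veg) > 5
  alc <- as.character(groups$alcohol) %in%
    c("never", "special_occasions", "one_to_three_monthly")
  alc[is.na(groups$alcohol)] <- NA
  score <- as.integer(meat) + as.integer(fv) + as.integer(alc)
  data.frame(
    wcrf_meat = meat, wcrf_fruit_veg = fv, wcrf_alcohol = alc,
    wcrf_score = score,
    wcrf_group = factor(ifelse(score >= 2, "2-3", "0-1"), levels = c("2-3", "0-1"))
  )
}

#' Derive inverse-variance weights from hazard-ratio estimates
#'
#' For each non-reference food category the weight is
#' \eqn{\ln(HR) / SE} with \eqn{SE = (\ln U - \ln L) / (2 \times 1.959964)}
#' recovered from the 95% confidence interval \eqn{(L, U)}.
#'
#' @param hr_estimates data.frame with columns `food`, `category`, `hr`,
#'   `lower`, `upper`.
#' @return the input with `log_hr`, `se`, `weight` appended.
#' @examples
#' derive_weight_table(data.frame(food = "red_meat", category = ">=3",
#'                                hr = 1.16, lower = 1.08, upper = 1.25))
#' @export
derive_weight_table <- function(hr_estimates) {
  h <- hr_estimates
  stopifnot(all(c("food", "category", "hr", "lower", "upper") %in% names(h)))
  if (any(!(h$lower <= h$hr & h$hr <= h$upper) | h$lower <= 0)) {
    stop("each confidence interval must satisfy 0 < lower <= HR <= upper")
  }
  h$log_hr <- log(h$hr)
  h$se <- (log(h$upper) - log(h$lower)) / (2 * z975)
  if (any(h$se <= 0)) stop("degenerate confidence interval (upper == lower)")
  h$weight <- ifelse(h$hr == 1, 0, h$log_hr / h$se)
  h
}

#' Default weight preset for the IV-weighted dietary score
#'
#' Adjusted hazard ratios (with 95% CIs) of the non-reference categories of
#' the eleven food groups against incident CRC, taken from published
#' large-cohort estimates and bundled as the package's default external
#' weight set.  Passed through [derive_weight_table()] to obtain
#' \eqn{\ln(HR)/SE} weights.
#'
#' @return weight table as returned by [derive_weight_table()].
#' @export
default_diet_weights <- function() {
  tab <- rbind(
    data.frame(food = "red_meat", category = c("2 to <3", ">=3"),
               hr = c(1.03, 1.16), lower = c(0.97, 1.08), upper = c(1.11, 1.25)),
    data.frame(food = "processed_meat", category = c("1", ">=2"),
               hr = c(1.06, 1.13), lower = c(0.99, 1.05), upper = c(1.14, 1.21)),
    data.frame(food = "poultry", category = c("1", ">=2"),
               hr = c(1.05, 1.02), lower = c(0.96, 0.94), upper = c(1.14, 1.11)),
    data.frame(food = "total_fish", category = c(">1 to <=2", ">2"),
               hr = c(1.05, 0.96), lower = c(0.98, 0.89), upper = c(1.13, 1.05)),
    data.frame(food = "milk", category = c("200 to <300", ">=300"),
               hr = c(0.91, 0.85), lower = c(0.85, 0.79), upper = c(0.97, 0.92)),
    data.frame(food = "cheese", category = c("2 to 4", ">=5"),
               hr = c(0.99, 1.05), lower = c(0.93, 0.95), upper = c(1.06, 1.15)),
    data.frame(food = "total_fruit", category = c("2 to <4", ">=4"),
               hr = c(0.93, 0.95), lower = c(0.87, 0.88), upper = c(1.00, 1.03)),
    data.frame(food = "total_veg", category = c("4 to <6", ">=6"),
               hr = c(1.00, 0.97), lower = c(0.93, 0.90), upper = c(1.07, 1.04)),
    data.frame(food = "coffee", category = c("1 to <=2", ">2"),
               hr = c(0.96, 1.01), lower = c(0.89, 0.93), upper = c(1.03, 1.08)),
    data.frame(food = "tea", category = c("3 to <5", ">=5"),
               hr = c(0.95, 0.88), lower = c(0.89, 0.82), upper = c(1.02, 0.94)),
    data.frame(food = "alcohol", category = c("1 to 2", ">=3"),
               hr = c(0.98, 1.08), lower = c(0.90, 1.01), upper = c(1.06, 1.17))
  )
  derive_weight_table(tab)
}

#' Inverse-variance-weighted dietary score
#'
#' Sums, over the eleven foods, the \eqn{\ln(HR)/SE} weight of the category
#' the participant falls in; reference categories contribute 0.  Participants
#' with any food category missing get NA.
#'
#' @param categories data.frame holding the `*_cat` columns produced by
#'   [derive_food_groups()].
#' @param weights weight table, e.g. [default_diet_weights()].
#' @return numeric vector of scores; the attainable (min, max) over all
#'   category combinations is attached as `attr(, "range")`.
#' @export
iv_diet_score <- function(categories, weights = default_diet_weights()) {
  cp <- diet_cutpoints()
  score <- numeric(nrow(categories))
  lo <- hi <- 0
  for (food in names(cp)) {
    col <- paste0(food, "_cat")
    if (!col %in% names(categories)) stop("missing category column: ", col)
    wf <- weights[weights$food == food, , drop = FALSE]
    labs <- cp[[food]]$labels
    miss_w <- setdiff(labs[-1], wf$category)
    if (length(miss_w)) {
      stop("weight table lacks category '", miss_w[1], "' for food ", food)
    }
    wvec <- c(0, wf$weight[match(labs[-1], wf$category)])
    names(wvec) <- labs
    score <- score + unname(wvec[as.character(categories[[col]])])
    lo <- lo + min(wvec); hi <- hi + max(wvec)
  }
  attr(score, "range") <- c(lo, hi)
  score
}

#' Read / write a diet weight table as TSV
#' @param path file path.
#' @rdname weight_table_io
#' @export
read_weight_table <- function(path) {
  derive_weight_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @param weights weight table.
#' @rdname weight_table_io
#' @export
write_weight_table <- function(weights, path) {
  utils::write.table(weights, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
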