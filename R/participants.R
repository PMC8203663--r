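# Participant/contact bookkeeping: parsing per-region contact-count strings
# of the form "2(L) 1(R)" and summarising a cohort table.

#' Parse a contact-count string
#'
#' Cohort tables record insulo-opercular contact counts per region as
#' strings like `"2(L) 2(R)"`, `"9(L)"` or `"0"`. Returns the left/right
#' counts.
#'
#' @param s character scalar.
#' @return named numeric vector `c(L = , R = )`.
#' @export
parse_contact_counts <- function(s) {
  out <- c(L = 0, R = 0)
  s <- trimws(s)
  if (s == "" || s == "0") return(out)
  m <- gregexpr("([0-9]+)\\(([LR])\\)", s)[[1]]
  if (m[1] == -1) stop_argument("unparseable contact count: '", s, "'")
  for (tok in regmatches(s, gregexpr("[0-9]+\\([LR]\\)", s))[[1]]) {
    n <- as.numeric(sub("\\(.*", "", tok))
    side <- sub(".*\\(([LR])\\).*", "\\1", tok)
    out[side] <- out[side] + n
  }
  out
}

#' Read a participant characteristics table
#'
#' TSV with columns `id`, `age`, `seizure_focus`, `bmi`, `palatable_rating`
#' (x of 10), `preferred_palatable`, and per-region contact-count strings
#' `frontal_operculum`, `ant_insula`, `pos_insula`.
#'
#' @param path TSV file; default is the cohort table shipped with the
#'   package.
#' @return data frame.
#' @export
read_participants <- function(path = system.file("extdata", "participants.tsv",
                                                 package = "foodcue")) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Summarise cohort contact counts and ratings
#'
#' Adds up the parsed per-region contact counts over all participants and
#' averages the palatable-solution ratings.
#'
#' @param participants [read_participants()] output.
#' @return list with `contacts_total`, `contacts_left`, `contacts_right`,
#'   per-region totals, and `mean_palatable_rating` (1 decimal).
#' @export
participant_summary <- function(participants = read_participants()) {
  region_cols <- c("frontal_operculum", "ant_insula", "pos_insula")
  per_region <- sapply(region_cols, function(col) {
    counts <- vapply(participants[[col]], parse_contact_counts, c(L = 0, R = 0))
    rowSums(counts)
  })
  left <- sum(per_region["L", ])
  right <- sum(per_region["R", ])
  list(contacts_total = left + right,
       contacts_left = left,
       contacts_right = right,
       contacts_by_region = colSums(per_region),
       mean_palatable_rating = round(mean(participants$palatable_rating), 1))
}
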