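#' Read an ortholog presence table
#'
#' @param path TSV with columns `gene`, `species` and optionally `present`
#'   (logical/0-1; rows with `present` false are dropped).
#' @return Named list mapping gene to a character vector of species.
#' @export
read_ortholog_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!all(c("gene", "species") %in% names(tab)))
    stop("ortholog table needs 'gene' and 'species' columns")
  if ("present" %in% names(tab)) tab <- tab[as.logical(tab$present), ]
  split(tab$species, tab$gene)
}

#' Read species divergence times
#'
#' @param path TSV with columns `species_a`, `species_b`, `myr`.
#' @return Symmetric named lookup usable by [estimate_age()]: a function is
#'   not returned, but a data.frame of the long-format pairs.
#' @export
read_divergence_times <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!all(c("species_a", "species_b", "myr") %in% names(tab)))
    stop("divergence table needs 'species_a', 'species_b', 'myr' columns")
  tab
}

# divergence time between reference and each species in `species`
divergence_to_reference <- function(times, reference, species) {
  if (is.data.frame(times)) {
    fwd <- times$myr[match(paste(reference, species),
                           paste(times$species_a, times$species_b))]
    rev <- times$myr[match(paste(reference, species),
                           paste(times$species_b, times$species_a))]
    out <- ifelse(is.na(fwd), rev, fwd)
    out[species == reference] <- 0
  } else {
    # named numeric vector of divergence times from the reference
    out <- unname(times[species])
    out[species == reference] <- 0
  }
  if (anyNA(out))
    stop("missing divergence time to reference for species: ",
         paste(species[is.na(out)], collapse = ", "))
  out
}

#' Estimate the age of a gene from its ortholog distribution
#'
#' The gene age is the divergence time between the reference species and
#' the most distantly related species carrying an ortholog. The estimate
#' is flagged `low` reliability when the ortholog distribution is patchy:
#' fewer than `min_frac` of the species younger than the oldest ortholog
#' (divergence strictly less than the age) also carry an ortholog.
#'
#' @param gene gene id present in `table`.
#' @param table ortholog table: named list gene -> species vector (see
#'   [read_ortholog_table()]).
#' @param times divergence times: long data.frame from
#'   [read_divergence_times()] or a named numeric vector of times from the
#'   reference.
#' @param reference reference species (default `"human"`).
#' @param species_universe species considered when assessing patchiness;
#'   defaults to every species named in `times`.
#' @param min_frac patchiness threshold (default 0.5).
#' @return List with `gene`, `age` (Myr), `oldest_ortholog_species`,
#'   `reliability` (`"high"`/`"low"`), `reference_only` flag.
#' @export
estimate_age <- function(gene, table, times, reference = "human",
                         species_universe = NULL, min_frac = 0.5) {
  if (!gene %in% names(table)) stop(sprintf("gene '%s' not in table", gene))
  orth <- unique(c(table[[gene]], reference))
  div <- divergence_to_reference(times, reference, orth)
  age <- max(div)
  oldest <- orth[which.max(div)]
  if (is.null(species_universe)) {
    species_universe <- if (is.data.frame(times))
      unique(c(times$species_a, times$species_b)) else names(times)
  }
  species_universe <- union(species_universe, reference)
  udiv <- divergence_to_reference(times, reference, species_universe)
  younger <- species_universe[udiv < age]
  frac <- if (length(younger)) mean(younger %in% orth) else 1
  list(gene = gene, age = age, oldest_ortholog_species = oldest,
       reliability = if (frac >= min_frac) "high" else "low",
       reference_only = length(setdiff(orth, reference)) == 0L)
}

#' Estimate ages for every gene in an ortholog table
#'
#' @inheritParams estimate_age
#' @return data.frame with one row per gene: `gene`, `age`,
#'   `oldest_ortholog_species`, `reliability`.
#' @export
estimate_ages <- function(table, times, reference = "human",
                          species_universe = NULL, min_frac = 0.5) {
  rows <- lapply(names(table), function(g) {
    e <- estimate_age(g, table, times, reference, species_universe, min_frac)
    data.frame(gene = g, age = e$age,
               oldest_ortholog_species = e$oldest_ortholog_species,
               reliability = e$reliability, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Screen genes whose age co-occurs with an ERV invasion window
#'
#' Candidates are genes whose estimated age falls within the invasion
#' profile's peak window widened by `tolerance` Myr on each side, sorted by
#' distance to the window midpoint.
#'
#' @param ages data.frame from [estimate_ages()] (columns `gene`, `age`).
#' @param profile [invasion_profile()] object (or a length-2 numeric window
#'   in Myr).
#' @param tolerance widening in Myr (default 10).
#' @return data.frame of candidates with `gene`, `age`, `distance` (to the
#'   window midpoint), sorted ascending by distance.
#' @export
cooccurrence_screen <- function(ages, profile, tolerance = 10) {
  window <- if (inherits(profile, "invasion_profile"))
    profile$peak_window else as.numeric(profile)
  lo <- window[1] - tolerance
  hi <- window[2] + tolerance
  mid <- mean(window)
  cand <- ages[ages$age >= lo & ages$age <= hi, , drop = FALSE]
  cand$distance <- abs(cand$age - mid)
  cand <- cand[order(cand$distance, cand$gene), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}
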