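#' Read a phylogeny in Newick format
#'
#' Thin, validating wrapper around [ape::read.tree()]. The tree is the
#' phylogenetic backbone of every downstream covariance computation, so the
#' reader enforces what those computations assume: a single rooted tree with
#' at least two uniquely labelled tips and non-negative branch lengths on
#' every edge.
#'
#' Zero-length terminal branches are legal (two tips then share an identical
#' row in the phylogenetic covariance matrix) but are flagged with a warning;
#' downstream matrix inversions add a small diagonal jitter when that happens.
#'
#' @param path Path to a Newick file containing one rooted tree.
#' @return An object of class `phylo`.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (inherits(tree, "multiPhylo")) {
    abort("`path` must contain a single Newick tree.")
  }
  if (is.null(tree)) abort(paste0("could not parse a Newick tree from ", path))
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort("not a `phylo` tree")
  if (ape::Ntip(tree) < 2) abort("tree must have at least 2 tips")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    abort(paste0("duplicate tip labels: ", paste(dup, collapse = ", ")))
  }
  if (is.null(tree$edge.length)) {
    abort("tree has no branch lengths; every edge must carry one")
  }
  if (anyNA(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge)) {
    bad <- which(is.na(tree$edge.length))
    abort(paste0("missing branch length on edge(s): ", paste(bad, collapse = ", ")))
  }
  if (any(tree$edge.length < 0)) {
    abort("negative branch lengths are not allowed")
  }
  term <- tree$edge[, 2] <= ape::Ntip(tree)
  if (any(tree$edge.length[term] == 0)) {
    warn("zero-length terminal branch(es): phylogenetic covariance will have repeated rows; a diagonal jitter is applied before inversion")
  }
  invisible(tree)
}

#' Write a phylogeny in Newick format
#'
#' @param tree A `phylo` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read the species trait table
#'
#' Expects a CSV with columns `species_id`, `one_c_pg` (genome size as a
#' 1C-value in picograms), `ploidy_class` (`"diploid"` or `"polyploid"`),
#' and either numeric columns `csr_c`, `csr_s`, `csr_r` (Grime strategy
#' proportions summing to 1) or a coded `csr` column (e.g. `"C"`, `"CSR"`,
#' `"C/CSR"`) translated through [csr_code_to_triple()]. Species reported
#' with a genome-size range may carry optional `one_c_min_pg` /
#' `one_c_max_pg` columns; downstream analyses always use `one_c_pg` (the
#' mean).
#'
#' @param path CSV file path.
#' @return A tibble with one row per species (a validated species table).
#' @export
read_species_table <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("species_id", "one_c_pg", "ploidy_class") %in% names(df))) {
    abort("species table needs columns species_id, one_c_pg, ploidy_class")
  }
  if (!all(c("csr_c", "csr_s", "csr_r") %in% names(df))) {
    if ("csr" %in% names(df)) {
      tri <- csr_code_to_triple(df$csr)
      df$csr_c <- tri$csr_c; df$csr_s <- tri$csr_s; df$csr_r <- tri$csr_r
    } else {
      abort("species table needs csr_c/csr_s/csr_r columns or a coded csr column")
    }
  }
  validate_species(df)
}

validate_species <- function(df) {
  df <- as_tibble(df)
  if (anyDuplicated(df$species_id)) abort("duplicate species_id in species table")
  if (any(!is.finite(df$one_c_pg)) || any(df$one_c_pg <= 0)) {
    abort("one_c_pg must be positive for every species")
  }
  if (!all(df$ploidy_class %in% c("diploid", "polyploid"))) {
    abort("ploidy_class must be 'diploid' or 'polyploid' for every species")
  }
  s <- df$csr_c + df$csr_s + df$csr_r
  bad <- which(abs(s - 1) > 1e-9 | df$csr_c < 0 | df$csr_s < 0 | df$csr_r < 0)
  if (length(bad)) {
    abort(paste0(
      "C:S:R triples must be non-negative and sum to 1; offending species: ",
      paste(df$species_id[bad], collapse = ", ")
    ))
  }
  df
}

#' Translate coded Grime strategies to C:S:R proportion triples
#'
#' Pure and intermediate Grime strategy codes are mapped to numeric
#' allocations: a pure letter gets the full unit mass, a multi-letter code
#' (e.g. `"CSR"`) splits it equally, and a slash code (e.g. `"C/CSR"`)
#' averages the triples on each side. This reproduces the conventional
#' numeric allocations used when published letter codes must be turned into
#' proportions for biomass partitioning.
#'
#' @param code Character vector of strategy codes.
#' @return A tibble with columns `csr_c`, `csr_s`, `csr_r`.
#' @export
#' @examples
#' csr_code_to_triple(c("C", "CSR", "C/CSR"))
csr_code_to_triple <- function(code) {
  one <- function(cd) {
    parts <- strsplit(toupper(cd), "/", fixed = TRUE)[[1]]
    tri <- vapply(parts, function(p) {
      letters <- strsplit(p, "")[[1]]
      if (!all(letters %in% c("C", "S", "R")) || length(letters) == 0) {
        abort(paste0("unrecognised C-S-R code: ", cd))
      }
      w <- c(C = 0, S = 0, R = 0)
      w[letters] <- 1 / length(letters)
      w
    }, numeric(3))
    rowMeans(tri)
  }
  m <- unname(t(vapply(code, one, numeric(3))))
  tibble(csr_c = m[, 1], csr_s = m[, 2], csr_r = m[, 3])
}

#' Read the subplot design table
#'
#' Expects a CSV with columns `plot_id`, `subplot_id`, `dose_nitrate`,
#' `dose_ammonium` (kg N ha^-1 yr^-1), logical/0-1 columns `p_applied`,
#' `k_applied`, `na_applied`, `mg_applied`, `si_applied`, and numeric `ph`.
#'
#' @param path CSV file path.
#' @return A validated design tibble, one row per subplot.
#' @export
read_design_table <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  validate_design(df)
}

validate_design <- function(df) {
  df <- as_tibble(df)
  need <- c("plot_id", "subplot_id", "dose_nitrate", "dose_ammonium",
            "p_applied", "k_applied", "na_applied", "mg_applied",
            "si_applied", "ph")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("design table missing columns: ", paste(miss, collapse = ", ")))
  if (anyDuplicated(df$subplot_id)) abort("duplicate subplot_id in design table")
  if (any(df$dose_nitrate < 0) || any(df$dose_ammonium < 0)) {
    abort("nutrient doses must be non-negative")
  }
  for (cl in c("p_applied", "k_applied", "na_applied", "mg_applied", "si_applied")) {
    df[[cl]] <- as.logical(df[[cl]])
    if (anyNA(df[[cl]])) abort(paste0(cl, " must be logical (TRUE/FALSE or 0/1)"))
  }
  df
}

#' Read the species-by-subplot biomass table
#'
#' Accepts either long format (columns `species_id`, `subplot_id`,
#' `biomass_g`) or wide format (a `species_id` column and one column per
#' subplot); wide input is pivoted to long. Zero biomass means the species
#' is absent from that subplot.
#'
#' @param path CSV file path.
#' @return A long tibble `species_id`, `subplot_id`, `biomass_g`.
#' @export
read_biomass_table <- function(path) {
  df <- as_tibble(read.csv(path, check.names = FALSE, stringsAsFactors = FALSE))
  if (!all(c("species_id", "subplot_id", "biomass_g") %in% names(df))) {
    if (!"species_id" %in% names(df)) {
      abort("biomass table needs species_id + subplot_id + biomass_g, or wide species_id x subplot columns")
    }
    df <- tidyr::pivot_longer(df, -"species_id",
                              names_to = "subplot_id", values_to = "biomass_g")
  }
  validate_biomass(df)
}

validate_biomass <- function(df) {
  df <- as_tibble(df)
  if (any(!is.finite(df$biomass_g))) abort("non-finite biomass values")
  if (any(df$biomass_g < 0)) {
    bad <- df[df$biomass_g < 0, ]
    abort(paste0("negative biomass for ",
                 paste(unique(bad$species_id), collapse = ", ")))
  }
  df
}

#' Cross-validate the three tables against each other
#'
#' Checks that every species and subplot appearing in the biomass table
#' resolves to a species / design record, and (optionally) that every
#' species is a tip of the tree. Species present in the biomass table but
#' lacking trait data are reported, not silently dropped.
#'
#' @param species,design,biomass Tibbles as returned by the readers.
#' @param tree Optional `phylo` to check tip coverage.
#' @return A list with the three validated tables and a character vector
#'   `missing_traits` of biomass species without trait records.
#' @export
validate_community <- function(species, design, biomass, tree = NULL) {
  species <- validate_species(species)
  design <- validate_design(design)
  biomass <- validate_biomass(biomass)
  missing_traits <- setdiff(unique(biomass$species_id), species$species_id)
  if (length(missing_traits)) {
    warn(paste0("species in biomass table without trait records: ",
                paste(missing_traits, collapse = ", ")))
  }
  orphan_sub <- setdiff(unique(biomass$subplot_id), design$subplot_id)
  if (length(orphan_sub)) {
    abort(paste0("biomass references unknown subplots: ",
                 paste(orphan_sub, collapse = ", ")))
  }
  if (!is.null(tree)) {
    off <- setdiff(species$species_id, tree$tip.label)
    if (length(off)) {
      warn(paste0("species not on the tree: ", paste(off, collapse = ", ")))
    }
  }
  list(species = species, design = design, biomass = biomass,
       missing_traits = missing_traits)
}

#' Write the three community tables to CSV
#'
#' Inverse of the readers: `read_*_table(write_community(...))` reproduces
#' the tables field-for-field.
#'
#' @param species,design,biomass Tibbles.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_community <- function(species, design, biomass, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    species = file.path(dir, "species.csv"),
    design = file.path(dir, "design.csv"),
    biomass = file.path(dir, "biomass.csv")
  )
  write.csv(species, paths[["species"]], row.names = FALSE)
  write.csv(design, paths[["design"]], row.names = FALSE)
  write.csv(biomass, paths[["biomass"]], row.names = FALSE)
  invisible(paths)
}
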