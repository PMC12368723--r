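# Mechanism definition files: schema, validation, round-trip IO.

# expected total reactant order implied by the units of a rate constant
.unit_order <- c("1/s" = 1, "m^3/(s*mol)" = 2, "m^6/(s*mol^2)" = 3)

#' Path to the canonical ibuprofen carbonylation mechanism file
#'
#' The shipped mechanism reconstructs the seven-step Pd-catalyzed route
#' (dehydration, hydrohalogenation, dehydrohalogenation, catalyst
#' activation, oxidative addition, carbonylation, hydrolysis) plus the
#' reversible esterification side reaction, with reactant orders dictated
#' by the units of the rate constants k1..k7, k8f, k8r.
#'
#' @return Path to the YAML mechanism file installed with the package.
#' @export
default_mechanism_path <- function() {
  system.file("extdata", "ibuprofen_mechanism.yaml", package = "ibuopt",
              mustWork = TRUE)
}

#' Load and validate a mechanism definition file
#'
#' A mechanism file is YAML with keys `species` (ordered list of
#' integrated species), `constant_species` (name -> fixed concentration in
#' mol/m^3), `rate_constants` (name -> unit string, one of `1/s`,
#' `m^3/(s*mol)`, `m^6/(s*mol^2)`), and `reactions`, each reaction a map
#' with `name`, `rate_constant`, `orders` (species -> nonnegative integer
#' reactant order) and `stoichiometry` (integrated species -> signed
#' change).  Validation enforces that every referenced species is
#' declared, every rate-constant reference is declared, and the total
#' reactant order of each reaction matches the units of its rate constant.
#'
#' @param path Path to a YAML mechanism file.
#' @return A `mechanism_spec` object.
#' @export
load_mechanism <- function(path) {
  if (!file.exists(path)) stop("mechanism file not found: ", path)
  raw <- yaml::read_yaml(path)
  mechanism_spec(
    species = as.character(raw$species),
    constant_species = unlist(raw$constant_species),
    rate_constants = unlist(raw$rate_constants),
    reactions = raw$reactions
  )
}

#' Construct and validate a mechanism specification
#'
#' @param species Character vector of integrated species names.
#' @param constant_species Named numeric vector of fixed concentrations
#'   (mol/m^3); may be `NULL`.
#' @param rate_constants Named character vector mapping rate-constant
#'   names to unit strings.
#' @param reactions List of reactions, each a list with elements `name`,
#'   `rate_constant`, `orders`, `stoichiometry`.
#' @return A `mechanism_spec` object: the validated inputs plus the
#'   assembled order matrix (reactions x all species) and stoichiometry
#'   matrix (reactions x integrated species).
#' @export
mechanism_spec <- function(species, constant_species = NULL,
                           rate_constants, reactions) {
  species <- as.character(species)
  if (anyDuplicated(species)) stop("duplicated species names")
  const_names <- names(constant_species)
  if (length(constant_species) && any(const_names %in% species))
    stop("constant species also listed as integrated species")
  all_species <- c(species, const_names)
  if (is.null(names(rate_constants)) || !length(rate_constants))
    stop("rate_constants must be a named map of name -> unit")
  unknown_units <- setdiff(unique(rate_constants), names(.unit_order))
  if (length(unknown_units))
    stop("unknown rate-constant units: ", paste(unknown_units, collapse = ", "))

  nr <- length(reactions)
  if (nr < 1L) stop("mechanism declares no reactions")
  ns <- length(species)
  O <- matrix(0, nr, length(all_species),
              dimnames = list(NULL, all_species))
  S <- matrix(0, nr, ns, dimnames = list(NULL, species))
  rnames <- character(nr)
  kref <- character(nr)
  for (j in seq_len(nr)) {
    rx <- reactions[[j]]
    rnames[j] <- if (is.null(rx$name)) paste0("reaction_", j) else rx$name
    bad <- function(msg) stop("reaction '", rnames[j], "': ", msg)
    if (is.null(rx$rate_constant)) bad("missing rate_constant")
    if (!rx$rate_constant %in% names(rate_constants))
      bad(paste0("undeclared rate constant '", rx$rate_constant, "'"))
    kref[j] <- rx$rate_constant
    ord <- unlist(rx$orders)
    sto <- unlist(rx$stoichiometry)
    if (!length(ord)) bad("empty reactant orders")
    if (!length(sto)) bad("empty stoichiometry")
    miss <- setdiff(names(ord), all_species)
    if (length(miss)) bad(paste0("orders cite undeclared species: ",
                                 paste(miss, collapse = ", ")))
    miss <- setdiff(names(sto), species)
    if (length(miss)) bad(paste0("stoichiometry cites undeclared or constant species: ",
                                 paste(miss, collapse = ", ")))
    if (any(ord < 0) || any(ord != round(ord)))
      bad("reactant orders must be nonnegative integers")
    expected <- .unit_order[[rate_constants[[rx$rate_constant]]]]
    if (sum(ord) != expected)
      bad(sprintf("total reactant order %d does not match the units of %s (expects order %d)",
                  sum(ord), rx$rate_constant, expected))
    O[j, names(ord)] <- ord
    S[j, names(sto)] <- sto
  }
  rownames(O) <- rownames(S) <- rnames

  structure(
    list(species = species,
         constant_species = constant_species,
         rate_constants = rate_constants,
         reactions = reactions,
         reaction_names = rnames,
         rate_constant_ref = kref,
         orders = O,
         stoich = S),
    class = "mechanism_spec")
}

#' Write a mechanism specification back to YAML
#'
#' `load_mechanism(write_mechanism(mech, path))` reproduces an identical
#' specification, so mechanism files round-trip.
#'
#' @param mech A `mechanism_spec`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mechanism <- function(mech, path) {
  stopifnot(inherits(mech, "mechanism_spec"))
  out <- list(
    species = mech$species,
    constant_species = as.list(mech$constant_species),
    rate_constants = as.list(mech$rate_constants),
    reactions = lapply(seq_along(mech$reactions), function(j) {
      rx <- mech$reactions[[j]]
      list(name = mech$reaction_names[j],
           rate_constant = mech$rate_constant_ref[j],
           orders = as.list(unlist(rx$orders)),
           stoichiometry = as.list(unlist(rx$stoichiometry)))
    })
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.mechanism_spec <- function(x, ...) {
  cat("<mechanism_spec> ", length(x$species), " integrated species, ",
      length(x$constant_species), " constant, ",
      nrow(x$orders), " reactions\n", sep = "")
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  if (length(x$constant_species))
    cat("  constant:", paste(names(x$constant_species),
                             x$constant_species, sep = "=", collapse = ", "), "\n")
  cat("  reactions:", paste(x$reaction_names, collapse = ", "), "\n")
  invisible(x)
}

# md5 of the canonical YAML serialization; used for dataset provenance
mechanism_hash <- function(mech) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_mechanism(mech, tmp)
  unname(tools::md5sum(tmp))
}
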