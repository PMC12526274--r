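#' Read a study configuration file
#'
#' Parses a YAML or JSON configuration into a [study_config()]. The file
#' mirrors the constructor arguments; synthetic progenies are given as a
#' list of records with `progeny_id`, `hybridization`, `n_leaves`,
#' `family`, `a`, `b`, `rwl`, `length_range`, `noise_sd`, `rwl_sd`,
#' `n_vertices` and `seed` (missing fields take the [progeny_spec()]
#' defaults). Alternatively `input` names a contour CSV/JSON file.
#'
#' @param path configuration file (`.yml`, `.yaml` or `.json`).
#' @return a [study_config()].
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(raw)) stop("config must be a mapping", call. = FALSE)

  progenies <- NULL
  if (!is.null(raw$progenies)) {
    progenies <- lapply(seq_along(raw$progenies), function(i) {
      p <- raw$progenies[[i]]
      get_or <- function(field, default) if (is.null(p[[field]])) default
                                         else p[[field]]
      shp <- shape_spec(family = get_or("family", "beta_profile"),
                        a = get_or("a", 1), b = get_or("b", 1),
                        rwl = get_or("rwl", 0.4))
      progeny_spec(progeny_id = get_or("progeny_id", as.character(i)),
                   hybridization = get_or("hybridization", "unknown"),
                   n_leaves = get_or("n_leaves", 228L), shape = shp,
                   length_range = unlist(get_or("length_range", c(5, 17))),
                   noise_sd = get_or("noise_sd", 0),
                   rwl_sd = get_or("rwl_sd", 0),
                   n_vertices = get_or("n_vertices", 256L),
                   seed = get_or("seed", i))
    })
  }
  get_top <- function(field, default) if (is.null(raw[[field]])) default
                                      else raw[[field]]
  bt <- get_top("bootstrap", list())
  get_bt <- function(field, default) if (is.null(bt[[field]])) default
                                     else bt[[field]]
  study_config(
    progenies = progenies, input = raw$input,
    bootstrap = bootstrap_config(B = get_bt("B", 10000L),
                                 level = get_bt("level", 0.95),
                                 seed = get_bt("seed", 1L)),
    references = utils::modifyList(list(h2 = 0.64340, h3 = 0.70125,
                                        h4 = 2 / 3, h5 = 2),
                                   get_top("references", list())),
    k_range = unlist(get_top("k_range", 2:6)),
    n_stations = get_top("n_stations", 2001L),
    stability_B = get_top("stability_B", 100L),
    gap_B = get_top("gap_B", 50L),
    output_dir = raw$output_dir)
}
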