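#' Write / read extended-XYZ configurations
#'
#' One frame per file: a count line, a comment line carrying
#' `Lattice="Lx 0 0 0 Ly 0 0 0 Lz"` and the column layout, then one row per
#' particle (`species x y z vx vy vz`).  Read-back reproduces the system.
#'
#' @param system A [particle_system()].
#' @param path File path.
#' @return `read_xyz()`: a [particle_system()].
#' @export
write_xyz <- function(system, path) {
  b <- system$box
  hdr <- sprintf(
    'Lattice="%.10g 0 0 0 %.10g 0 0 0 %.10g" Properties=species:S:1:pos:R:3:vel:R:3',
    b[1], b[2], b[3])
  rows <- sprintf("%s %.10g %.10g %.10g %.10g %.10g %.10g", system$species,
                  system$positions[, 1], system$positions[, 2],
                  system$positions[, 3], system$velocities[, 1],
                  system$velocities[, 2], system$velocities[, 3])
  writeLines(c(as.character(nrow(system$positions)), hdr, rows), path)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  m <- regmatches(lines[2], regexec('Lattice="([^"]+)"', lines[2]))[[1]]
  if (length(m) < 2) stop("missing Lattice in extended-XYZ header", call. = FALSE)
  lat <- as.numeric(strsplit(trimws(m[2]), "\\s+")[[1]])
  box <- lat[c(1, 5, 9)]
  fields <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  spc <- vapply(fields, `[[`, character(1), 1)
  num <- t(vapply(fields, function(f) as.numeric(f[2:7]), numeric(6)))
  particle_system(num[, 1:3], spc, box, num[, 4:6])
}

#' Write / read LAMMPS-dump-style text frames
#'
#' Plain-text dump with columns `id type x y z vx vy vz`; `type` is the
#' species index in the order W, H, T, O.
#'
#' @param system A [particle_system()].
#' @param path File path.
#' @param step Timestep number recorded in the header.
#' @return `read_lammps_dump()`: a [particle_system()].
#' @export
write_lammps_dump <- function(system, path, step = 0) {
  n <- nrow(system$positions)
  b <- system$box
  lines <- c("ITEM: TIMESTEP", as.character(step),
             "ITEM: NUMBER OF ATOMS", as.character(n),
             "ITEM: BOX BOUNDS pp pp pp",
             sprintf("0 %.10g", b[1]), sprintf("0 %.10g", b[2]),
             sprintf("0 %.10g", b[3]),
             "ITEM: ATOMS id type x y z vx vy vz",
             sprintf("%d %d %.10g %.10g %.10g %.10g %.10g %.10g",
                     seq_len(n), species_codes(system),
                     system$positions[, 1], system$positions[, 2],
                     system$positions[, 3], system$velocities[, 1],
                     system$velocities[, 2], system$velocities[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_lammps_dump
#' @export
read_lammps_dump <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[which(lines == "ITEM: NUMBER OF ATOMS") + 1])
  bi <- which(lines == "ITEM: BOX BOUNDS pp pp pp")
  box <- vapply(1:3, function(d)
    diff(as.numeric(strsplit(lines[bi + d], "\\s+")[[1]])), numeric(1))
  ai <- which(startsWith(lines, "ITEM: ATOMS"))
  dat <- utils::read.table(text = lines[(ai + 1):(ai + n)])
  dat <- dat[order(dat[[1]]), ]
  particle_system(as.matrix(dat[, 3:5]), SPECIES[dat[[2]]], box,
                  as.matrix(dat[, 6:8]))
}

#' Read a YAML run configuration
#'
#' A single file covering the stage selector (`fit`, `simulate-trace`,
#' `md-equilibrate`, `nemd-shear`, `friction`, `morphology`), stage-specific
#' parameter blocks, the global seed and the output directory.
#'
#' @param path YAML file.
#' @return A named list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stages <- c("fit", "simulate-trace", "md-equilibrate", "nemd-shear",
              "friction", "morphology")
  if (is.null(cfg$stage) || !cfg$stage %in% stages)
    stop("config must name a stage in: ", paste(stages, collapse = ", "),
         call. = FALSE)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  structure(cfg, class = "run_config", path = path)
}

#' Write a provenance log for a run
#'
#' Records the configuration hash (MD5 of the serialized configuration), the
#' seed, the package version and a timestamp as JSON, so any result can be
#' regenerated from its recorded config + seed.
#'
#' @param config The configuration object (any serializable R object).
#' @param seed Integer seed used.
#' @param path Output JSON path.
#' @param extra Optional named list appended to the log.
#' @return The log (invisibly).
#' @export
provenance_log <- function(config, seed, path, extra = list()) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp)
  log <- c(list(config_hash = unname(tools::md5sum(tmp)),
                seed = as.integer(seed),
                package_version = as.character(utils::packageVersion("sidmr")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
           extra)
  writeLines(as.character(jsonlite::toJSON(log, auto_unbox = TRUE, digits = NA)),
             path)
  invisible(log)
}
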