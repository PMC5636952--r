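# Readers and writers. Datasets and trajectories travel as multi-frame
# extended XYZ (per-frame comment line with key=value fields: energy in
# kcal/mol, total_charge in e, dipole in Debye; per-atom columns element,
# x, y, z and optionally fx, fy, fz). Models serialize to a self-describing
# versioned JSON document. Spectra are two-column text.

.fmt <- function(x) sprintf("%.12g", x)

#' Write a dataset to extended XYZ
#'
#' @param dataset List of \code{atomic_config}s (labels optional).
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_dataset <- function(dataset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (d in dataset) {
    n <- n_atoms(d)
    props <- if (is.null(d$forces)) "species:S:1:pos:R:3"
             else "species:S:1:pos:R:3:forces:R:3"
    fields <- c(sprintf("Properties=%s", props),
                "units=ang_fs_kcalmol_e_debye")
    if (!is.null(d$energy)) {
      fields <- c(fields, sprintf("energy=%s", .fmt(d$energy)))
    }
    if (!is.null(d$total_charge)) {
      fields <- c(fields, sprintf("total_charge=%s", .fmt(d$total_charge)))
    }
    if (!is.null(d$dipole)) {
      fields <- c(fields, sprintf('dipole="%s"',
                                  paste(.fmt(d$dipole), collapse = " ")))
    }
    writeLines(as.character(n), con)
    writeLines(paste(fields, collapse = " "), con)
    for (i in seq_len(n)) {
      row <- c(d$elements[i], .fmt(d$positions[i, ]))
      if (!is.null(d$forces)) row <- c(row, .fmt(d$forces[i, ]))
      writeLines(paste(row, collapse = " "), con)
    }
  }
  invisible(path)
}

# parse key=value tokens honoring double quotes
.parse_comment <- function(line) {
  out <- list()
  pat <- '([A-Za-z_][A-Za-z0-9_]*)=("[^"]*"|\\S+)'
  m <- gregexpr(pat, line, perl = TRUE)[[1]]
  if (m[1] == -1) return(out)
  for (tok in regmatches(line, gregexpr(pat, line, perl = TRUE))[[1]]) {
    eq <- regexpr("=", tok)
    key <- substr(tok, 1, eq - 1)
    val <- substr(tok, eq + 1, nchar(tok))
    val <- gsub('^"|"$', "", val)
    out[[key]] <- val
  }
  out
}

#' Read a dataset from extended XYZ
#'
#' Inverse of \code{\link{write_dataset}}; round-trips all labels to text
#' precision. Frames with missing forces are returned without a
#' \code{forces} entry (not an error); malformed frames raise an error
#' naming the offending line.
#'
#' @param path Input file path.
#' @return List of \code{atomic_config}s.
#' @export
read_dataset <- function(path) {
  lines <- readLines(path)
  out <- list()
  ln <- 1L
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln]))) { ln <- ln + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(n) || n < 1) {
      stop("expected an atom count at line ", ln, " of ", path)
    }
    if (ln + 1L + n > length(lines)) {
      stop("truncated frame starting at line ", ln, " of ", path)
    }
    meta <- .parse_comment(lines[ln + 1L])
    with_forces <- grepl("forces", meta$Properties %||% "")
    rows <- strsplit(trimws(lines[(ln + 2L):(ln + 1L + n)]), "\\s+")
    ncols <- if (with_forces) 7L else 4L
    bad <- which(vapply(rows, length, 0L) < ncols)
    if (length(bad)) {
      stop("malformed atom line ", ln + 1L + bad[1], " of ", path)
    }
    el <- vapply(rows, `[[`, "", 1L)
    num <- t(vapply(rows, function(r)
      suppressWarnings(as.numeric(r[2:ncols])), numeric(ncols - 1L)))
    if (anyNA(num)) stop("non-numeric field in frame at line ", ln, " of ", path)
    cfg <- atomic_config(
      el, num[, 1:3, drop = FALSE],
      energy = if (!is.null(meta$energy)) as.numeric(meta$energy),
      forces = if (with_forces) num[, 4:6, drop = FALSE],
      dipole = if (!is.null(meta$dipole))
        as.numeric(strsplit(trimws(meta$dipole), "\\s+")[[1]]),
      total_charge = if (!is.null(meta$total_charge))
        as.numeric(meta$total_charge))
    out[[length(out) + 1L]] <- cfg
    ln <- ln + 2L + n
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trajectory as multi-frame extended XYZ
#'
#' @param traj A \code{trajectory}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_trajectory <- function(traj, path) {
  dataset <- lapply(seq_along(traj$frames), function(k)
    atomic_config(traj$elements, traj$frames[[k]],
                  energy = traj$energies[k],
                  dipole = if (!is.null(traj$dipoles)) traj$dipoles[k, ]))
  write_dataset(dataset, path)
}

#' Serialize a model to JSON
#'
#' Self-describing, versioned document holding the descriptor
#' parameterization, input scalings, energy shifts and per-element weights.
#' Works for \code{hdnnp} and \code{dipole_model}.
#'
#' @param model The model.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_model <- function(model, path) {
  p <- model$descriptor_params
  doc <- list(
    schema = "nnpir-model",
    version = 1L,
    class = class(model),
    descriptor_params = list(
      elements = p$elements, cutoff = p$cutoff,
      radial = as.list(p$radial), angular = as.list(p$angular)),
    hidden = model$hidden,
    seed = model$seed,
    energy_shifts = as.list(model$energy_shifts),
    scaling = model$scaling,
    networks = lapply(model$networks, function(net)
      list(sizes = net$sizes, W = lapply(net$W, as.vector), b = net$b)))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a model from JSON
#'
#' @param path Path written by \code{\link{write_model}}.
#' @return An \code{hdnnp} or \code{dipole_model}.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "nnpir-model")) {
    stop("not an nnpir model file: ", path)
  }
  dp <- doc$descriptor_params
  params <- descriptor_params(
    dp$elements, cutoff = dp$cutoff,
    radial_eta = dp$radial$eta, radial_rs = dp$radial$rs,
    angular_eta = unique(dp$angular$eta),
    angular_zeta = unique(dp$angular$zeta),
    angular_lambda = unique(dp$angular$lambda))
  ctor <- if ("dipole_model" %in% doc$class) dipole_model else hdnnp
  model <- ctor(params, hidden = doc$hidden, seed = doc$seed)
  for (e in names(model$networks)) {
    net <- model$networks[[e]]
    nd <- doc$networks[[e]]
    for (l in seq_along(net$W)) {
      net$W[[l]] <- matrix(unlist(nd$W[[l]]), nrow(net$W[[l]]),
                           ncol(net$W[[l]]))
      net$b[[l]] <- as.numeric(nd$b[[l]])
    }
    model$networks[[e]] <- net
    model$scaling[[e]] <- list(
      center = as.numeric(doc$scaling[[e]]$center),
      scale = as.numeric(doc$scaling[[e]]$scale))
  }
  model$energy_shifts[] <- unlist(doc$energy_shifts)[names(model$networks)]
  model
}

#' Write a spectrum as two-column text
#'
#' @param spectrum An \code{ir_spectrum}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.table(
    data.frame(wavenumber_cm1 = spectrum$wavenumber,
               intensity = spectrum$intensity),
    path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
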