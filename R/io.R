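#' Default run configuration
#'
#' The flat key/value schema used by [read_config()] and the command-line
#' interface. Every figure-class experiment is reproducible from one of
#' these documents plus a seed.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    experiment = "wrinkle",      # wrinkle | compress | pack
    L_x = 45, L_y = 720, L_z = 90,
    boundary_x = "wall", boundary_y = "periodic", boundary_z = "periodic",
    phi = 0.16,
    alpha = 2, radius = 2, K = 2, s_b = 0.08, s_ba = 0.08,
    delta_c = NULL, delta_d = NULL, delta_ca = NULL,
    zeta = 1, D_c = 0, dt = NULL,
    cell_cell_adhesion = TRUE, cell_agar_adhesion = TRUE,
    W_D = NULL, H_D = 27, cdp_image = NULL,
    ablation_mode = "abrupt", n_stages = 10, relax_steps = 200,
    homog_steps = 2000, weak_scale = 0.1, pre_relax_steps = 20000,
    v_threshold = 0.01, max_steps = 50000,
    voxel = 20, mesh_size = 20,
    delta_L = NULL, n_increments = 8,
    seed = 1, out_dir = "."
  )
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected by name; missing keys take the defaults of
#' [default_config()]; the parameter invariants (alpha > 1,
#' delta_c <= delta_d, positive thresholds) are enforced by constructing the
#' [model_params()] and [sim_box()] objects.
#'
#' @param path YAML file.
#' @return object of class \code{run_config} (a named list).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  defaults <- default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, user, keep.null = TRUE)
  config_objects(cfg)  # validation side effect
  structure(cfg, class = c("run_config", "list"))
}

#' Write a configuration as YAML
#'
#' Round-trips through [read_config()]: NULL-valued keys (auto-computed
#' defaults) are omitted.
#'
#' @param cfg a \code{run_config} or plain named list.
#' @param path output file.
#' @export
write_config <- function(cfg, path) {
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# Materialize box / params / cdp from a config list.
config_objects <- function(cfg) {
  box <- sim_box(cfg$L_x, cfg$L_y, cfg$L_z,
                 cfg$boundary_x, cfg$boundary_y, cfg$boundary_z)
  params <- model_params(alpha = cfg$alpha, radius = cfg$radius, K = cfg$K,
                         s_b = cfg$s_b, s_ba = cfg$s_ba,
                         delta_c = cfg$delta_c, delta_d = cfg$delta_d,
                         delta_ca = cfg$delta_ca, zeta = cfg$zeta,
                         D_c = cfg$D_c, dt = cfg$dt,
                         cell_cell_adhesion = cfg$cell_cell_adhesion,
                         cell_agar_adhesion = cfg$cell_agar_adhesion)
  cdp <- NULL
  if (!is.null(cfg$cdp_image)) {
    cdp <- image_cdp(cfg$cdp_image, cfg$H_D, box)
  } else if (!is.null(cfg$W_D) && cfg$W_D > 0) {
    cdp <- rect_cdp(cfg$W_D, cfg$H_D, box)
  }
  list(box = box, params = params, cdp = cdp)
}

snapshot_header <- function(state) {
  c("# wrinklesim snapshot",
    "# units: lengths um, time s, forces K*um; x is height, agar at x = 0",
    sprintf("# box: %g %g %g boundary: %s %s %s",
            state$box$L[1], state$box$L[2], state$box$L[3],
            state$box$boundary[1], state$box$boundary[2],
            state$box$boundary[3]),
    sprintf("# time: %g", state$time))
}

#' Write a snapshot of a simulation state
#'
#' Formats: \code{"csv"} (commented header with box, boundaries and time,
#' then id, x, y, z, radius, sigma_hyd) and \code{"xyz"} (extended XYZ, one
#' frame: the comment line carries the lattice, per-atom properties and
#' time). The \code{sigma_hyd} column is the hydrostatic stress from
#' [per_agent_stress()].
#'
#' @param state a [sim_state()].
#' @param path output file.
#' @param format "csv" or "xyz"; default guessed from the extension.
#' @return the path, invisibly.
#' @export
write_snapshot <- function(state, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "csv"
  format <- match.arg(format, c("csv", "xyz"))
  df <- snapshot(state, stress = n_agents(state) > 0)
  if (n_agents(state) == 0) df$sigma_hyd <- numeric(0)
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(snapshot_header(state), con)
    write.csv(df, con, row.names = FALSE)
  } else {
    lat <- sprintf('Lattice="%g 0 0 0 %g 0 0 0 %g"',
                   state$box$L[1], state$box$L[2], state$box$L[3])
    props <- "Properties=species:S:1:pos:R:3:radius:R:1:id:I:1:sigma_hyd:R:1"
    comment <- sprintf('%s %s Time=%g Boundary="%s %s %s"', lat, props,
                       state$time, state$box$boundary[1],
                       state$box$boundary[2], state$box$boundary[3])
    lines <- c(sprintf("%d", nrow(df)), comment,
               sprintf("C %.10g %.10g %.10g %.10g %d %.10g",
                       df$x, df$y, df$z, df$radius, df$id, df$sigma_hyd))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a snapshot written by [write_snapshot()]
#'
#' @param path snapshot file (csv or extended xyz, by extension).
#' @return data.frame with id, x, y, z, radius, sigma_hyd; attributes
#'   \code{box_L}, \code{boundary} and \code{time} carry the header
#'   metadata.
#' @export
read_snapshot <- function(path) {
  if (grepl("\\.xyz$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    n <- as.integer(lines[1])
    comment <- lines[2]
    lat <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
    L <- as.numeric(strsplit(sub('Lattice="([^"]*)"', "\\1", lat), " ")[[1]])
    L <- L[c(1, 5, 9)]
    tm <- as.numeric(sub('.*Time=([0-9eE.+-]+).*', "\\1", comment))
    bd <- sub('.*Boundary="([^"]*)".*', "\\1", comment)
    df <- if (n > 0) {
      parts <- strsplit(lines[3:(2 + n)], " +")
      m <- do.call(rbind, lapply(parts, function(p) as.numeric(p[2:7])))
      data.frame(id = as.integer(m[, 5]), x = m[, 1], y = m[, 2], z = m[, 3],
                 radius = m[, 4], sigma_hyd = m[, 6])
    } else {
      data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                 z = numeric(0), radius = numeric(0), sigma_hyd = numeric(0))
    }
    attr(df, "box_L") <- L
    attr(df, "boundary") <- strsplit(bd, " ")[[1]]
    attr(df, "time") <- tm
    df
  } else {
    hdr <- readLines(path, n = 10)
    hdr <- hdr[startsWith(hdr, "#")]
    df <- read.csv(path, comment.char = "#")
    bx <- hdr[grepl("^# box:", hdr)]
    if (length(bx)) {
      parts <- strsplit(sub("^# box: ", "", bx), " ")[[1]]
      attr(df, "box_L") <- as.numeric(parts[1:3])
      attr(df, "boundary") <- parts[5:7]
    }
    tl <- hdr[grepl("^# time:", hdr)]
    if (length(tl)) attr(df, "time") <- as.numeric(sub("^# time: ", "", tl))
    df
  }
}
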