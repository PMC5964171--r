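# File formats: structured-text (JSON) model files, OpenSim storage/motion
# export, a subset importer for OpenSim model XML, and delimited-text
# readers/writers for marker and force trials.

#' Write a model to a structured-text (JSON) file
#'
#' Full-precision JSON serialization of segments, coordinates, MTU
#' parameters and via-point geometry; [read_model()] round-trips the model
#' bit-exactly.
#'
#' @param model a `hindlimb_model`.
#' @param path output file.
#' @export
write_model <- function(model, path) {
  obj <- list(
    format = "mousegait-model",
    version = 1L,
    gravity = model$gravity,
    foot_cop = model$foot_cop,
    segments = model$segments,
    coordinates = model$coordinates,
    mtus = lapply(model$mtus, function(m)
      list(params = m$params,
           path = list(via = m$path$via, spanned = m$path$spanned,
                       primary = m$path$primary,
                       primary_sign = m$path$primary_sign)))
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a model from a structured-text (JSON) file
#'
#' @param path file written by [write_model()].
#' @return a `hindlimb_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  if (!identical(obj$format, "mousegait-model"))
    stop_mousegait("mousegait_input_error", "not a mousegait model file")
  mtus <- lapply(obj$mtus, function(m) {
    list(params = as.list(m$params),
         path = list(via = as.data.frame(m$path$via),
                     spanned = unlist(m$path$spanned),
                     primary = m$path$primary,
                     primary_sign = m$path$primary_sign))
  })
  structure(list(segments = as.data.frame(obj$segments),
                 coordinates = as.data.frame(obj$coordinates),
                 mtus = mtus, gravity = obj$gravity,
                 foot_cop = unlist(obj$foot_cop)),
            class = "hindlimb_model")
}

#' Import a subset of an OpenSim model (.osim) file
#'
#' Parses what this package can represent from the OpenSim XML model
#' format: body mass properties (`mass`, `mass_center`, `inertia`), muscle
#' force-generating parameters of Thelen/Millard-type muscles
#' (`max_isometric_force`, `optimal_fiber_length`, `tendon_slack_length`,
#' `pennation_angle_at_optimal`), and muscle path points. Unsupported
#' elements are skipped and their tag names reported.
#'
#' @param path .osim file path.
#' @return list with `bodies` (data.frame), `muscles` (data.frame),
#'   `path_points` (data.frame muscle/body/x/y/z), `skipped` (character).
#' @export
read_osim <- function(path) {
  doc <- xml2::read_xml(path)
  num <- function(x) as.numeric(strsplit(trimws(x), "\\s+")[[1]])
  body_nodes <- xml2::xml_find_all(doc, ".//BodySet//Body")
  bodies <- do.call(rbind, lapply(body_nodes, function(b) {
    g <- function(tag) {
      txt <- xml2::xml_text(xml2::xml_find_first(b, tag))
      if (is.na(txt)) NA_character_ else txt
    }
    mc_txt <- g("mass_center")
    mc <- if (is.na(mc_txt)) c(0, 0, 0) else num(mc_txt)
    inert <- xml2::xml_find_first(b, "inertia")
    iv <- if (!is.na(inert)) num(xml2::xml_text(inert)) else {
      vapply(c("inertia_xx", "inertia_yy", "inertia_zz"),
             function(tag) as.numeric(g(tag)), numeric(1))
    }
    data.frame(name = xml2::xml_attr(b, "name"),
               mass = as.numeric(g("mass")),
               com_x = mc[1], com_y = mc[2], com_z = mc[3],
               ixx = iv[1], iyy = iv[2], izz = iv[3],
               stringsAsFactors = FALSE)
  }))
  muscle_types <- c("Thelen2003Muscle", "Millard2012EquilibriumMuscle",
                    "Schutte1993Muscle")
  mnodes <- xml2::xml_find_all(
    doc, paste(sprintf(".//%s", muscle_types), collapse = " | "))
  muscles <- do.call(rbind, lapply(mnodes, function(m) {
    g <- function(tag) {
      node <- xml2::xml_find_first(m, tag)
      if (is.na(node)) NA_real_ else as.numeric(xml2::xml_text(node))
    }
    data.frame(name = xml2::xml_attr(m, "name"),
               f_max = g("max_isometric_force"),
               l_opt = g("optimal_fiber_length"),
               l_ts = g("tendon_slack_length"),
               pennation0 = rad2deg(g("pennation_angle_at_optimal")),
               stringsAsFactors = FALSE)
  }))
  pnodes <- xml2::xml_find_all(doc, ".//PathPoint")
  path_points <- do.call(rbind, lapply(pnodes, function(p) {
    loc <- num(xml2::xml_text(xml2::xml_find_first(p, "location")))
    muscle <- xml2::xml_attr(
      xml2::xml_find_first(p, sprintf("ancestor::*[%s]",
        paste(sprintf("self::%s", muscle_types), collapse = " or "))),
      "name")
    body_node <- xml2::xml_find_first(p, "body|socket_parent_frame")
    data.frame(muscle = muscle %||% NA_character_,
               body = if (is.na(body_node)) NA_character_
                      else trimws(xml2::xml_text(body_node)),
               x = loc[1], y = loc[2], z = loc[3],
               stringsAsFactors = FALSE)
  }))
  known <- c("Body", "PathPoint", muscle_types)
  all_tags <- unique(xml2::xml_name(xml2::xml_find_all(doc, ".//*")))
  skipped <- setdiff(all_tags, c(known, "BodySet", "objects"))
  list(bodies = bodies, muscles = muscles, path_points = path_points,
       skipped = skipped)
}

#' Write a series table in OpenSim storage (.sto/.mot) format
#'
#' @param x data.frame whose first column is `time`.
#' @param path output file.
#' @param name header name field.
#' @param in_degrees value of the `inDegrees` header flag.
#' @export
write_sto <- function(x, path, name = "mousegait", in_degrees = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(name,
               sprintf("version=1"),
               sprintf("nRows=%d", nrow(x)),
               sprintf("nColumns=%d", ncol(x)),
               sprintf("inDegrees=%s", if (in_degrees) "yes" else "no"),
               "endheader",
               paste(names(x), collapse = "\t")), con)
  utils::write.table(format(x, digits = 15, trim = TRUE), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an OpenSim storage (.sto/.mot) table
#'
#' @param path file path.
#' @return data.frame of the tabular block.
#' @export
read_sto <- function(path) {
  lines <- readLines(path)
  end <- which(trimws(lines) == "endheader")
  if (!length(end))
    stop_mousegait("mousegait_input_error", "no endheader line in file")
  utils::read.table(text = paste(lines[-seq_len(end[1])], collapse = "\n"),
                    header = TRUE, sep = "\t")
}

#' Write / read a marker trial as delimited text
#'
#' Columns: `time`, then `<label>_x`, `<label>_y` per marker label; a `#`
#' header line records the frame rate.
#'
#' @param trial a `marker_trial`.
#' @param path file path.
#' @export
write_marker_trial <- function(trial, path) {
  tab <- data.frame(time = trial$time)
  for (lb in names(trial$markers)) {
    tab[[paste0(lb, "_x")]] <- trial$markers[[lb]][, 1]
    tab[[paste0(lb, "_y")]] <- trial$markers[[lb]][, 2]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mousegait marker trial; frame_rate=%.10g Hz",
                     trial$frame_rate), con)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_marker_trial
#' @export
read_marker_trial <- function(path) {
  header <- readLines(path, n = 1)
  fr <- as.numeric(sub(".*frame_rate=([0-9.eE+-]+).*", "\\1", header))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  labels <- unique(sub("_[xy]$", "", setdiff(names(tab), "time")))
  markers <- lapply(labels, function(lb)
    cbind(tab[[paste0(lb, "_x")]], tab[[paste0(lb, "_y")]]))
  names(markers) <- labels
  marker_trial(tab$time, markers, fr)
}

#' Write / read a force-plate trial as delimited text
#'
#' Columns `time`, `f_craniocaudal`, `f_vertical`; the `#` header line
#' records the stance window.
#'
#' @param trial a `force_plate_trial`.
#' @param path file path.
#' @export
write_force_trial <- function(trial, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mousegait force trial; stance=%.10g %.10g",
                     trial$stance_window[1], trial$stance_window[2]), con)
  utils::write.table(
    data.frame(time = trial$time, f_craniocaudal = trial$f_craniocaudal,
               f_vertical = trial$f_vertical),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_force_trial
#' @export
read_force_trial <- function(path) {
  header <- readLines(path, n = 1)
  sw <- as.numeric(strsplit(sub(".*stance=", "", header), "\\s+")[[1]])
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  force_plate_trial(tab$time, tab$f_craniocaudal, tab$f_vertical, sw)
}
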