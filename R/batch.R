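# Minimal non-interactive batch orchestration: split a hierarchical
# dataset into independent per-patient, per-fraction jobs, run them with
# isolated failure handling and atomic output writes, and merge
# per-fraction outputs into accumulated DSMs and an EUD table.
#
# Dataset layout:
#   root/plan.txt                      helical plan (shared)
#   root/calibration.csv               MV calibration table
#   root/patients/<id>/planning/ct/    planning kV DICOM series
#   root/patients/<id>/planning/struct/rectum.dcm
#   root/patients/<id>/fractions/<NNN>/mv/   MV series with shift/roll tags
# Outputs land under .../fractions/<NNN>/out/ and .../<id>/out/.

#' Plan per-fraction jobs for a dataset
#'
#' One job per usable fraction per stage; fractions whose MV headers carry
#' the skip tag get status `"skipped"`, and jobs whose output already
#' exists get `"done"` and are not re-queued by [run_jobs()].
#'
#' @param root dataset root directory.
#' @param stages subset of `c("dose", "segment", "dsm")`.
#' @return data frame of job specifications.
#' @export
plan_jobs <- function(root, stages = c("dose", "segment", "dsm")) {
  stages <- match.arg(stages, c("dose", "segment", "dsm"),
                      several.ok = TRUE)
  pat_dir <- file.path(root, "patients")
  patients <- if (dir.exists(pat_dir))
    sort(list.dirs(pat_dir, recursive = FALSE)) else character(0)
  jobs <- list()
  for (pd in patients) {
    frs <- sort(list.dirs(file.path(pd, "fractions"), recursive = FALSE))
    for (fd in frs) {
      usable <- tryCatch({
        mv <- read_ct_series(file.path(fd, "mv"))
        read_registration(mv)$usable
      }, error = function(e) NA)
      for (st in stages) {
        out <- file.path(fd, "out", switch(st, dose = "dose.dcm",
                                           segment = "rectum_mv.dcm",
                                           dsm = "dsm.csv"))
        status <- if (isFALSE(usable)) "skipped"
          else if (file.exists(out)) "done" else "pending"
        jobs[[length(jobs) + 1L]] <- data.frame(
          patient = basename(pd), fraction = basename(fd), stage = st,
          input = fd, output = out, status = status,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(jobs))
    return(data.frame(patient = character(0), fraction = character(0),
                      stage = character(0), input = character(0),
                      output = character(0), status = character(0)))
  do.call(rbind, jobs)
}

# atomic write: produce the file under a temp name, then rename
.atomic <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- paste0(path, ".tmp", Sys.getpid())
  writer(tmp)
  file.rename(tmp, path)
}

.run_one_job <- function(job, root, config) {
  pd <- file.path(root, "patients", job$patient)
  mv <- read_ct_series(file.path(job$input, "mv"))
  reg <- read_registration(mv)
  if (!reg$usable) return("skipped")
  switch(job$stage,
    dose = {
      plan <- read_plan(file.path(root, "plan.txt"))
      tab <- read_calibration_table(file.path(root, "calibration.csv"))
      cal_mv <- select_calibration(mv$acquisition_date, mv$machine_id, tab)
      kv <- read_ct_series(file.path(pd, "planning", "ct"))
      aligned <- align_kv(kv, reg, plan$isocentre)
      masked <- mask_scan_circle(aligned,
                                 scan_circle(plan$isocentre,
                                             config$scan_circle_diameter))
      cube <- compute_fraction_dose(plan, mv, masked, reg, cal_mv,
                                    downsample = config$downsample)
      .atomic(job$output, function(p) write_dose(cube, p))
    },
    segment = {
      cs <- read_structure_set(file.path(pd, "planning", "struct",
                                         "rectum.dcm"))
      seg <- segment_scan(mv, cs, config$seg_params, reg,
                          isocentre = config$isocentre)
      .atomic(job$output, function(p) write_structure_set(seg, p))
    },
    dsm = {
      dose_path <- file.path(job$input, "out", "dose.dcm")
      seg_path <- file.path(job$input, "out", "rectum_mv.dcm")
      if (!file.exists(dose_path) || !file.exists(seg_path))
        stop("dsm stage needs dose and segment outputs for fraction ",
             job$fraction)
      cube <- read_dose(dose_path)
      cs <- read_structure_set(seg_path)
      dsm <- build_fraction_dsm(cs, cube, n_theta = config$n_theta,
                                dz = reg$dz)
      .atomic(job$output, function(p) write_dsm_csv(dsm, p))
    })
  "done"
}

#' Default pipeline configuration
#'
#' @param downsample in-plane dose-grid downsampling factor.
#' @param n_theta DSM sample points per row.
#' @param scan_circle_diameter MV field-of-view diameter, mm.
#' @param isocentre in-plane isocentre, mm.
#' @param seg_params a [seg_params()].
#' @param eud_a gEUD parameter used in the merged EUD table.
#' @return named list.
#' @export
batch_config <- function(downsample = 4, n_theta = 21,
                         scan_circle_diameter = 386, isocentre = c(0, 0),
                         seg_params = NULL, eud_a = 8) {
  if (is.null(seg_params)) seg_params <- voxcalc::seg_params()
  list(downsample = downsample, n_theta = n_theta,
       scan_circle_diameter = scan_circle_diameter, isocentre = isocentre,
       seg_params = seg_params, eud_a = eud_a)
}

#' Run planned jobs
#'
#' Jobs run independently in a fixed order (patient, fraction, stage);
#' stages within a fraction respect their natural order because `dsm`
#' consumes the `dose` and `segment` outputs.  A failing job is recorded
#' and isolated -- it never stops the others.  Outputs are written
#' atomically (temp file + rename), so the result is identical for any
#' worker count; `n_workers > 1` parallelises over patients.
#'
#' @param jobs data frame from [plan_jobs()].
#' @param root dataset root.
#' @param config list from [batch_config()].
#' @param n_workers worker processes (forked; 1 = serial).
#' @return the jobs data frame with updated `status` and an `error`
#'   column; attribute `report` holds per-status counts.
#' @export
run_jobs <- function(jobs, root, config = batch_config(), n_workers = 1) {
  if (!nrow(jobs)) {
    attr(jobs, "report") <- table(character(0))
    return(jobs)
  }
  stage_rank <- c(dose = 1, segment = 2, dsm = 3)
  jobs <- jobs[order(jobs$patient, jobs$fraction,
                     stage_rank[jobs$stage]), , drop = FALSE]
  jobs$error <- NA_character_
  run_patient <- function(pat) {
    sub <- jobs[jobs$patient == pat, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      if (sub$status[i] != "pending") next
      res <- tryCatch(.run_one_job(sub[i, ], root, config),
                      error = function(e) structure(conditionMessage(e),
                                                    class = "job_error"))
      if (inherits(res, "job_error")) {
        sub$status[i] <- "failed"; sub$error[i] <- unclass(res)
      } else sub$status[i] <- res
    }
    sub
  }
  pats <- unique(jobs$patient)
  out <- if (n_workers > 1) {
    parallel::mclapply(pats, run_patient, mc.cores = n_workers)
  } else {
    lapply(pats, run_patient)
  }
  jobs <- do.call(rbind, out)
  rownames(jobs) <- NULL
  attr(jobs, "report") <- table(factor(jobs$status,
                                       c("pending", "done", "failed",
                                         "skipped")))
  jobs
}

# planning dose + DSM for a patient (cached under the patient out/ dir):
# the per-fraction planned dose on the planning CT with zero registration
.planning_dsm <- function(root, patient, config) {
  pd <- file.path(root, "patients", patient)
  cache <- file.path(pd, "out", "planning_dsm.csv")
  if (file.exists(cache)) return(read_dsm_csv(cache))
  plan <- read_plan(file.path(root, "plan.txt"))
  kv <- read_ct_series(file.path(pd, "planning", "ct"))
  cs <- read_structure_set(file.path(pd, "planning", "struct",
                                     "rectum.dcm"))
  cube <- compute_fraction_dose(plan, kv, NULL, registration(),
                                cal_mv = kv_calibration(),
                                downsample = config$downsample)
  dsm <- build_fraction_dsm(cs, cube, n_theta = config$n_theta, dz = 0)
  dsm$provenance <- "planning"
  .atomic(cache, function(p) write_dsm_csv(dsm, p))
  dsm
}

#' Merge per-fraction outputs for one patient
#'
#' Accumulates the per-fraction DSMs (planning rows padding the ends of
#' the short MV scans) and writes the accumulated DSM plus a summary row
#' with planned and delivered gEUD.  Refuses to merge while a usable
#' fraction lacks its DSM output, naming the fraction.
#'
#' @param root dataset root.
#' @param patient patient id.
#' @param config list from [batch_config()].
#' @return list with `dsm` (accumulated [dose_surface_map()]) and
#'   `summary` (one-row data frame).
#' @export
merge_outputs <- function(root, patient, config = batch_config()) {
  pd <- file.path(root, "patients", patient)
  frs <- sort(list.dirs(file.path(pd, "fractions"), recursive = FALSE))
  dsms <- list()
  for (fd in frs) {
    mv <- read_ct_series(file.path(fd, "mv"))
    if (!read_registration(mv)$usable) next
    f <- file.path(fd, "out", "dsm.csv")
    if (!file.exists(f))
      stop("missing DSM output for fraction ", basename(fd),
           " of patient ", patient)
    dsms[[length(dsms) + 1L]] <- read_dsm_csv(f)
  }
  if (!length(dsms)) stop("no usable fractions for patient ", patient)
  planning <- .planning_dsm(root, patient, config)
  extent <- range(planning$row_si)
  acc <- accumulate_dsms(dsms, planning, extent)
  n <- length(dsms)
  planned_total <- planning
  planned_total$values <- planning$values * n
  summary <- data.frame(patient = patient, n_fractions = n,
                        planned_eud = geud(planned_total, config$eud_a),
                        delivered_eud = geud(acc, config$eud_a))
  summary$relative_eud <- summary$delivered_eud / summary$planned_eud
  dir.create(file.path(pd, "out"), showWarnings = FALSE, recursive = TRUE)
  .atomic(file.path(pd, "out", "accumulated_dsm.csv"),
          function(p) write_dsm_csv(acc, p))
  .atomic(file.path(pd, "out", "eud.csv"),
          function(p) utils::write.csv(summary, p, row.names = FALSE))
  list(dsm = acc, summary = summary)
}

#' Merge every patient and write the cohort EUD table
#'
#' @param root dataset root.
#' @param config list from [batch_config()].
#' @return data frame with one summary row per patient (also written to
#'   `root/eud_table.csv`).
#' @export
merge_all <- function(root, config = batch_config()) {
  pats <- sort(basename(list.dirs(file.path(root, "patients"),
                                  recursive = FALSE)))
  tab <- do.call(rbind, lapply(pats, function(p)
    merge_outputs(root, p, config)$summary))
  .atomic(file.path(root, "eud_table.csv"),
          function(p) utils::write.csv(tab, p, row.names = FALSE))
  tab
}

#' Write a synthetic pelvis dataset in the batch layout
#'
#' Generates `n_patients` pelvis phantom series (seeds `seed`, `seed + 1`,
#' ...) and writes them as DICOM series plus the shared plan and
#' calibration files, ready for [plan_jobs()].
#'
#' @param root target directory.
#' @param n_patients number of patients.
#' @param spec_fn function(seed) returning a [pelvis_spec()]; the default
#'   uses a compact geometry suited to pipeline runs.
#' @param plan a [helical_plan()] (default: geometric prostate plan).
#' @param seed base seed.
#' @return `root`, invisibly.
#' @export
write_pelvis_dataset <- function(root, n_patients = 3,
                                 spec_fn = NULL, plan = NULL, seed = 1) {
  if (is.null(spec_fn))
    spec_fn <- function(s) pelvis_spec(
      seed = s, n_fractions = 4, mv_size = 96, mv_spacing = 4,
      mv_slices = 6, kv_size = 112, kv_spacing = 4, kv_slices = 31,
      rectum_z_extent = c(-51, 51))
  if (is.null(plan)) plan <- make_prostate_plan(n_rotations = 4, pitch = 15)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  write_plan(plan, file.path(root, "plan.txt"))
  file.copy(system.file("extdata", "mv_calibration.csv",
                        package = "voxcalc", mustWork = TRUE),
            file.path(root, "calibration.csv"), overwrite = TRUE)
  for (i in seq_len(n_patients)) {
    spec <- spec_fn(seed + i - 1)
    series <- make_pelvis_series(spec)
    pd <- file.path(root, "patients", sprintf("P%03d", i))
    write_ct_series(series$planning_kv, file.path(pd, "planning", "ct"))
    dir.create(file.path(pd, "planning", "struct"), recursive = TRUE,
               showWarnings = FALSE)
    write_structure_set(series$planning_contours,
                        file.path(pd, "planning", "struct", "rectum.dcm"))
    for (f in seq_along(series$fractions)) {
      fr <- series$fractions[[f]]
      write_ct_series(fr$mv,
                      file.path(pd, "fractions", sprintf("%03d", f), "mv"),
                      reg = fr$reg)
    }
  }
  invisible(root)
}
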