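#' Construct a death-certificate record
#'
#' A record mirrors the structure of an electronic death certificate: Part I
#' holds up to four free-text fields describing the chain of events leading
#' directly to death (field 1 the immediate cause, the last the underlying
#' one); Part II optionally lists other contributing conditions. Clinical
#' bulletins and autopsy reports accompany deaths from violent or unknown
#' causes, and coders may leave free-text annotations. Gender and age are the
#' structured covariates fed to the model; the ISO week of death supports
#' surveillance time series. Gold labels, when present, are the
#' manually-assigned underlying cause of death (`gold_ucod`) and the full set
#' of causes (`gold_causes`).
#'
#' @param part1 character vector, 1 to 4 non-empty free-text cause fields.
#' @param part2,bulletin,autopsy,annotations optional free text (`NULL` if absent).
#' @param gender `"male"`, `"female"` or `"unknown"`.
#' @param age non-negative age in years, or `NA` when unknown.
#' @param week ISO week of death (integer), or `NA`.
#' @param gold_ucod gold underlying-cause code, or `NA`.
#' @param gold_causes character vector of gold multiple-cause codes, or `NULL`.
#' @param id optional record identifier.
#' @return An object of class `certificate`.
#' @export
certificate <- function(part1, part2 = NULL, bulletin = NULL, autopsy = NULL,
                        annotations = NULL, gender = "unknown", age = NA,
                        week = NA, gold_ucod = NA_character_,
                        gold_causes = NULL, id = NA_character_) {
  part1 <- as.character(part1)
  if (length(part1) < 1L || length(part1) > 4L || any(!nzchar(part1))) {
    stop("part1 must contain 1 to 4 non-empty fields")
  }
  if (!gender %in% c("male", "female", "unknown")) {
    stop("gender must be male, female or unknown")
  }
  if (!is.na(age) && age < 0) stop("age must be non-negative")
  structure(
    list(id = id, part1 = part1, part2 = part2, bulletin = bulletin,
         autopsy = autopsy, annotations = annotations, gender = gender,
         age = if (is.na(age)) NA_real_ else as.numeric(age),
         week = if (is.na(week)) NA_integer_ else as.integer(week),
         gold_ucod = gold_ucod,
         gold_causes = if (is.null(gold_causes)) NULL else as.character(gold_causes)),
    class = "certificate"
  )
}

#' @export
print.certificate <- function(x, ...) {
  cat("<certificate>", if (!is.na(x$id)) x$id else "", "\n")
  cat("  part I:", paste(x$part1, collapse = " | "), "\n")
  if (!is.null(x$part2)) cat("  part II:", x$part2, "\n")
  cat(sprintf("  gender=%s age=%s week=%s gold=%s\n",
              x$gender, x$age, x$week, x$gold_ucod))
  invisible(x)
}

#' Read certificates from a JSON-lines file
#'
#' One JSON object per line with the field names of [certificate()].
#'
#' @param path file path.
#' @return List of `certificate` objects.
#' @export
read_certificates <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    certificate(
      part1 = x$part1,
      part2 = x$part2, bulletin = x$bulletin, autopsy = x$autopsy,
      annotations = x$annotations,
      gender = if (is.null(x$gender)) "unknown" else x$gender,
      age = if (is.null(x$age)) NA else x$age,
      week = if (is.null(x$week)) NA else x$week,
      gold_ucod = if (is.null(x$gold_ucod)) NA_character_ else x$gold_ucod,
      gold_causes = x$gold_causes,
      id = if (is.null(x$id)) NA_character_ else x$id
    )
  })
}

#' Write certificates to a JSON-lines file
#'
#' @param records list of `certificate` objects.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_certificates <- function(records, path) {
  lines <- vapply(records, function(r) {
    keep <- r[!vapply(r, function(v) is.null(v) || (length(v) == 1 && is.na(v)),
                      logical(1))]
    jsonlite::toJSON(keep, auto_unbox = TRUE, null = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Default prompt template
#'
#' A template fixes the textual scaffolding around a record: a contextual
#' preamble about the coding scenario, a natural-language label per field, a
#' task instruction per supported task and the output prefix after which the
#' model generates. Rendering is deterministic; absent optional fields are
#' omitted rather than rendered empty, while unknown age or gender is rendered
#' as an explicit "unknown" phrase, since certificates genuinely lacking this
#' information exist and the model should see that state.
#'
#' @param language `"en"` or `"pt"`.
#' @return An object of class `prompt_template`.
#' @export
default_template <- function(language = c("en", "pt")) {
  language <- match.arg(language)
  if (language == "en") {
    t <- list(
      preamble = "death certificate for coding the underlying cause of death .",
      labels = c(part1 = "part one :", part2 = "part two :",
                 bulletin = "clinical bulletin :", autopsy = "autopsy report :",
                 annotations = "coder notes :", gender = "gender :",
                 age = "age :"),
      unknown = "unknown",
      instructions = c(ucod = "assign the code of the underlying cause of death .",
                       causes = "assign the codes of all causes of death ."),
      output_prefix = "answer :",
      echo_separator = "<sep>",
      causes_delimiter = "<sep>"
    )
  } else {
    t <- list(
      preamble = "certificado de obito para codificacao da causa basica de morte .",
      labels = c(part1 = "parte um :", part2 = "parte dois :",
                 bulletin = "boletim clinico :", autopsy = "relatorio de autopsia :",
                 annotations = "notas do codificador :", gender = "sexo :",
                 age = "idade :"),
      unknown = "desconhecido",
      instructions = c(ucod = "atribuir o codigo da causa basica de morte .",
                       causes = "atribuir os codigos de todas as causas de morte ."),
      output_prefix = "resposta :",
      echo_separator = "<sep>",
      causes_delimiter = "<sep>"
    )
  }
  structure(t, class = "prompt_template")
}

#' Load a template from a YAML file
#' @param path YAML file with the fields of [default_template()].
#' @return A `prompt_template`.
#' @export
load_template <- function(path) {
  x <- yaml::read_yaml(path)
  base <- unclass(default_template("en"))
  for (nm in names(x)) {
    if (nm %in% c("labels", "instructions")) {
      base[[nm]][names(unlist(x[[nm]]))] <- unlist(x[[nm]])
    } else {
      base[[nm]] <- x[[nm]]
    }
  }
  structure(base, class = "prompt_template")
}

#' Render a certificate into a textual prompt
#'
#' The prompt contains, in template order: the preamble, every present field
#' under its label, the covariates (gender and age), the task instruction, and
#' finally the output prefix. Two identical records render to byte-identical
#' prompts.
#'
#' @param record a `certificate`.
#' @param template a `prompt_template`.
#' @param task `"ucod"` or `"causes"`.
#' @return A single prompt string.
#' @export
render_prompt <- function(record, template = default_template(),
                          task = c("ucod", "causes")) {
  task <- match.arg(task)
  if (!task %in% names(template$instructions)) {
    stop("configuration error: task not supported by template: ", task)
  }
  parts <- c(template$preamble,
             paste(template$labels["part1"], paste(record$part1, collapse = " ; ")))
  for (f in c("part2", "bulletin", "autopsy", "annotations")) {
    if (!is.null(record[[f]]) && nzchar(record[[f]])) {
      parts <- c(parts, paste(template$labels[f], record[[f]]))
    }
  }
  parts <- c(parts,
             paste(template$labels["gender"],
                   if (record$gender == "unknown") template$unknown else record$gender),
             paste(template$labels["age"],
                   if (is.na(record$age)) template$unknown else record$age),
             template$instructions[[task]],
             template$output_prefix)
  paste(parts, collapse = " ")
}

#' Render a certificate into a full training text
#'
#' The training text is the prompt followed by the gold generation target --
#' the descriptive title of the gold underlying cause, or the titles of all
#' gold causes joined by the configured delimiter -- and the end-of-sequence
#' marker. During causal training the loss is applied to all tokens of this
#' text, prompt included, not only to the expected output.
#'
#' @param record a `certificate` carrying the gold label(s) for `task`.
#' @param template a `prompt_template`.
#' @param task `"ucod"` or `"causes"`.
#' @param catalog a `code_catalog` used to map gold codes to titles.
#' @return A single training text string.
#' @export
render_training_text <- function(record, template, task = c("ucod", "causes"),
                                 catalog) {
  task <- match.arg(task)
  prompt <- render_prompt(record, template, task)
  if (task == "ucod") {
    if (is.na(record$gold_ucod)) stop("data error: record has no gold_ucod")
    idx <- catalog$by_code[record$gold_ucod]
    if (is.na(idx)) stop("gold code not in catalog: ", record$gold_ucod)
    target <- catalog$entries$title[idx]
  } else {
    if (is.null(record$gold_causes)) stop("data error: record has no gold_causes")
    idx <- catalog$by_code[record$gold_causes]
    if (anyNA(idx)) {
      stop("gold cause code(s) not in catalog: ",
           paste(record$gold_causes[is.na(idx)], collapse = ", "))
    }
    target <- paste(catalog$entries$title[idx],
                    collapse = paste0(" ", template$causes_delimiter, " "))
  }
  paste(prompt, target, "<eos>")
}
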