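# Minimal single-sheet xlsx writer (Office Open XML). Strings are written as
# inline strings, numbers as numeric cells; enough for a flat phenotype table
# and readable by any spreadsheet tool.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

col_letter <- function(i) {
  out <- character(length(i))
  for (k in seq_along(i)) {
    n <- i[k]; s <- ""
    while (n > 0) { r <- (n - 1) %% 26; s <- paste0(LETTERS[r + 1], s); n <- (n - 1) %/% 26 }
    out[k] <- s
  }
  out
}

sheet_xml <- function(df) {
  header <- paste0(
    '<row r="1">',
    paste0('<c r="', col_letter(seq_along(df)), '1" t="inlineStr"><is><t>',
           xml_escape(names(df)), "</t></is></c>", collapse = ""),
    "</row>")
  rows <- vapply(seq_len(nrow(df)), function(i) {
    cells <- vapply(seq_along(df), function(j) {
      v <- df[[j]][i]
      ref <- paste0(col_letter(j), i + 1L)
      if (is.na(v) || (is.character(v) && !nzchar(v))) return("")
      if (is.numeric(v)) {
        paste0('<c r="', ref, '"><v>', format(v, digits = 15, scientific = FALSE), "</v></c>")
      } else {
        paste0('<c r="', ref, '" t="inlineStr"><is><t>', xml_escape(as.character(v)),
               "</t></is></c>")
      }
    }, "")
    paste0('<row r="', i + 1L, '">', paste0(cells, collapse = ""), "</row>")
  }, "")
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
         "<sheetData>", header, paste0(rows, collapse = ""), "</sheetData></worksheet>")
}

write_xlsx_minimal <- function(df, path, sheet_name = "phenotypes") {
  stopifnot(is.data.frame(df))
  dir <- tempfile("xlsx")
  dir.create(file.path(dir, "_rels"), recursive = TRUE)
  dir.create(file.path(dir, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(dir, "xl", "worksheets"), recursive = TRUE)

  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    "</Types>"), file.path(dir, "[Content_Types].xml"))

  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    "</Relationships>"), file.path(dir, "_rels", ".rels"))

  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets><sheet name="', xml_escape(sheet_name), '" sheetId="1" r:id="rId1"/></sheets></workbook>'),
    file.path(dir, "xl", "workbook.xml"))

  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
    "</Relationships>"), file.path(dir, "xl", "_rels", "workbook.xml.rels"))

  writeLines(sheet_xml(df), file.path(dir, "xl", "worksheets", "sheet1.xml"))

  if (file.exists(path)) unlink(path)
  old <- getwd(); on.exit(setwd(old), add = TRUE)
  setwd(dir)
  zip::zip(zipfile = "out.xlsx",
           files = c("[Content_Types].xml", "_rels/.rels", "xl/workbook.xml",
                     "xl/_rels/workbook.xml.rels", "xl/worksheets/sheet1.xml"),
           mode = "mirror")
  setwd(old)
  file.copy(file.path(dir, "out.xlsx"), path, overwrite = TRUE)
  unlink(dir, recursive = TRUE)
  invisible(path)
}
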