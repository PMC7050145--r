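"""Convert a per-category XLSX supplementary workbook to candidate TSV.

Sheets named with a single category letter A-J (optionally decorated, e.g.
"(B)" or "B - Energy metabolism") are ingested; each sheet's first row is
the header. Headers are normalized tolerantly to the canonical TSV schema.
"""
import re
import sys

import openpyxl

ALIASES = {
    "protein": "protein_id", "proteinid": "protein_id", "id": "protein_id",
    "gene": "gene_id", "geneid": "gene_id",
    "targetp11": "targetp", "psort": "psort2", "psortii": "psort2",
    "predotar104": "predotar",
    "aasequence": "protein_seq", "proteinsequence": "protein_seq",
    "codingsequence": "cds_seq", "cds": "cds_seq",
}


def norm(h):
    key = re.sub(r"[^a-z0-9]", "", str(h).lower())
    return ALIASES.get(key, re.sub(r"\s+", "_", str(h).strip().lower()))


def sheet_category(title):
    m = re.search(r"\b([A-J])\b", title)
    return m.group(1) if m else None


def main(src, dst):
    wb = openpyxl.load_workbook(src, read_only=True, data_only=True)
    rows_out = []
    header_out = []
    for ws in wb.worksheets:
        cat = sheet_category(ws.title)
        if cat is None:
            continue
        rows = ws.iter_rows(values_only=True)
        try:
            header = [norm(h) for h in next(rows)]
        except StopIteration:
            continue
        for col in header:
            if col not in header_out:
                header_out.append(col)
        for row in rows:
            if all(v is None for v in row):
                continue
            rec = dict(zip(header, row))
            rec["category"] = cat
            rows_out.append(rec)
    if "category" not in header_out:
        header_out.append("category")
    with open(dst, "w", encoding="utf-8") as fh:
        fh.write("\t".join(header_out) + "\n")
        for rec in rows_out:
            vals = [rec.get(c) for c in header_out]
            fh.write("\t".join("." if v is None else str(v) for v in vals) + "\n")


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
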