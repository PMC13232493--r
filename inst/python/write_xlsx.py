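"""Render typed JSON sheet data to a multi-sheet .xlsx workbook.

Usage: python write_xlsx.py <sheets.json> <out.xlsx>

The JSON carries, per sheet, the sheet name, ordered column names, a type
tag per column (num/bool/str) and row objects keyed by column name; null
cells stay empty. Kept deliberately dumb: all table logic lives upstream.
"""
import json
import sys

import openpyxl


def main(json_path, out_path):
    with open(json_path) as fh:
        data = json.load(fh)
    wb = openpyxl.Workbook()
    wb.remove(wb.active)
    for sheet in data["sheets"]:
        ws = wb.create_sheet(title=sheet["name"])
        cols = sheet["columns"]
        types = dict(zip(cols, sheet["types"]))
        ws.append(cols)
        for row in sheet["rows"]:
            out = []
            for col in cols:
                v = row.get(col)
                if v is None:
                    out.append(None)
                elif types[col] == "bool":
                    out.append(bool(v))
                elif types[col] == "num":
                    out.append(float(v))
                else:
                    out.append(str(v))
            ws.append(out)
    wb.save(out_path)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
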