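"""Batch SPARQL runner: loads Turtle files into an rdflib graph per job and
executes SELECT queries, writing all result tables as one JSON document.

Usage: python sparql_runner.py <jobs.json> <out.json>

jobs.json: {"jobs": [{"name": ..., "files": [...], "queries": {qname: sparql}}]}
out.json:  {name: {qname: {"cols": [...], "rows": [[...]]}}}
"""
import json
import sys

import rdflib


def main(job_path, out_path):
    with open(job_path) as fh:
        spec = json.load(fh)
    out = {}
    for job in spec["jobs"]:
        g = rdflib.Graph()
        for f in job["files"]:
            g.parse(f, format="turtle")
        res = {}
        for name, q in job["queries"].items():
            r = g.query(q)
            cols = [str(v) for v in r.vars]
            rows = [[None if cell is None else str(cell) for cell in row]
                    for row in r]
            res[name] = {"cols": cols, "rows": rows}
        out[job["name"]] = res
    with open(out_path, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
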