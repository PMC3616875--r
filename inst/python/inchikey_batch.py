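"""Batch Standard InChI -> InChIKey via the InChI library bundled with RDKit.

Reads one InChI per line from argv[1]; writes one line per input to argv[2]:
the 27-character key, or an empty line when generation fails.
"""
import sys

from rdkit import RDLogger
from rdkit.Chem import inchi

RDLogger.DisableLog("rdApp.*")


def main(infile, outfile):
    with open(infile, encoding="utf-8") as fh:
        lines = fh.read().split("\n")
    if lines and lines[-1] == "":
        lines.pop()
    out = []
    for s in lines:
        key = ""
        if s.startswith("InChI=1S/"):
            try:
                key = inchi.InchiToInchiKey(s) or ""
            except Exception:
                key = ""
        if len(key) != 27:
            key = ""
        out.append(key)
    with open(outfile, "w", encoding="utf-8") as fh:
        fh.write("\n".join(out) + ("\n" if out else ""))


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
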