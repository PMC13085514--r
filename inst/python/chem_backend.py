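"""RDKit batch backend for the dt50prob R package.

Reads a JSON request from argv[1], writes a JSON response to argv[2].

Request:  {"op": <str>, "smiles": [<str>, ...], "options": {...}}
Response: {"ok": true, "results": [<per-smiles record>, ...]}

Per-smiles records always carry "ok"; on parse failure "ok" is false and
"error" holds a short reason. Stereochemistry is removed during
standardization; isotope labels are kept (isotopomers stay distinct).
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors, MACCSkeys
from rdkit.Avalon import pyAvalonTools

RDLogger.DisableLog("rdApp.*")

ORGANIC_SET = {"H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I"}


def parse(smi):
    if not isinstance(smi, str) or smi.strip() == "":
        return None
    return Chem.MolFromSmiles(smi)


def standardize_one(smi):
    mol = parse(smi)
    if mol is None:
        return {"ok": False, "error": "unparsable SMILES"}
    Chem.RemoveStereochemistry(mol)
    return {"ok": True, "canonical": Chem.MolToSmiles(mol)}


def profile_one(smi):
    mol = parse(smi)
    if mol is None:
        return {"ok": False, "error": "unparsable SMILES"}
    Chem.RemoveStereochemistry(mol)
    elements = sorted({a.GetSymbol() for a in mol.GetAtoms()})
    return {
        "ok": True,
        "canonical": Chem.MolToSmiles(mol),
        "mw": Descriptors.MolWt(mol),
        "n_fragments": len(Chem.GetMolFrags(mol)),
        "elements": elements,
        "has_carbon": "C" in elements,
        "non_organic": sorted(set(elements) - ORGANIC_SET),
    }


def fingerprint_one(smi, fp_type, n_bits):
    mol = parse(smi)
    if mol is None:
        return {"ok": False, "error": "unparsable SMILES"}
    if fp_type == "maccs":
        bv = MACCSkeys.GenMACCSKeys(mol)  # 167 bits, bit 0 unused
        on = [b for b in bv.GetOnBits()]
        return {"ok": True, "n_bits": 166, "on_bits": [b - 1 for b in on if b >= 1]}
    if fp_type == "avalon":
        bv = pyAvalonTools.GetAvalonFP(mol, nBits=n_bits)
    elif fp_type == "rdk":
        bv = Chem.RDKFingerprint(mol, fpSize=n_bits)
    elif fp_type == "morgan":
        bv = AllChem.GetMorganFingerprintAsBitVect(mol, 2, nBits=n_bits)
    else:
        return {"ok": False, "error": "unknown fingerprint type %s" % fp_type}
    return {"ok": True, "n_bits": n_bits, "on_bits": list(bv.GetOnBits())}


def descriptors_one(smi, names):
    if isinstance(names, str):
        names = [names]
    mol = parse(smi)
    if mol is None:
        return {"ok": False, "error": "unparsable SMILES"}
    vals = Descriptors.CalcMolDescriptors(mol)
    if names:
        vals = {k: vals.get(k) for k in names}
    out = {}
    for k, v in vals.items():
        try:
            v = float(v)
        except (TypeError, ValueError):
            v = None
        if v is not None and (v != v or v in (float("inf"), float("-inf"))):
            v = None
        out[k] = v
    return {"ok": True, "descriptors": out}


def main():
    with open(sys.argv[1]) as fh:
        req = json.load(fh)
    op = req["op"]
    smiles = req.get("smiles", [])
    opt = req.get("options", {}) or {}
    if op == "standardize":
        results = [standardize_one(s) for s in smiles]
    elif op == "profile":
        results = [profile_one(s) for s in smiles]
    elif op == "fingerprint":
        fp_type = opt.get("fp_type", "morgan")
        n_bits = int(opt.get("n_bits", 2048))
        results = [fingerprint_one(s, fp_type, n_bits) for s in smiles]
    elif op == "descriptors":
        names = opt.get("names")
        results = [descriptors_one(s, names) for s in smiles]
    else:
        json.dump({"ok": False, "error": "unknown op %s" % op}, open(sys.argv[2], "w"))
        return 1
    with open(sys.argv[2], "w") as fh:
        json.dump({"ok": True, "results": results}, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main())
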