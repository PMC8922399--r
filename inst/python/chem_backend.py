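#!/usr/bin/env python
"""Batch chemistry backend for the mtqsar R package.

Reads one JSON request from argv[1], writes one JSON reply to argv[2].
Every operation is batched over a list of SMILES so that a single
interpreter start-up serves many molecules.  All heavy lifting is RDKit.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Draw, MACCSkeys, QED
from rdkit.Chem.Draw import rdMolDraw2D
from rdkit.Chem.MolStandardize import rdMolStandardize

RDLogger.DisableLog("rdApp.*")

HYB = {
    Chem.HybridizationType.SP: "SP",
    Chem.HybridizationType.SP2: "SP2",
    Chem.HybridizationType.SP3: "SP3",
    Chem.HybridizationType.SP3D: "SP3D",
    Chem.HybridizationType.SP3D2: "SP3D2",
}
CHIRAL = {
    Chem.ChiralType.CHI_TETRAHEDRAL_CW: "CW",
    Chem.ChiralType.CHI_TETRAHEDRAL_CCW: "CCW",
}
BOND = {
    Chem.BondType.SINGLE: "SINGLE",
    Chem.BondType.DOUBLE: "DOUBLE",
    Chem.BondType.TRIPLE: "TRIPLE",
    Chem.BondType.AROMATIC: "AROMATIC",
}
STEREO = {
    Chem.BondStereo.STEREOZ: "Z",
    Chem.BondStereo.STEREOE: "E",
    Chem.BondStereo.STEREOCIS: "Z",
    Chem.BondStereo.STEREOTRANS: "E",
}


def op_standardize(req):
    """Normalize, keep the largest organic fragment, neutralize charges,
    return the canonical SMILES.  Unparseable input -> ok False + reason."""
    uncharger = rdMolStandardize.Uncharger()
    out = []
    for smi in req["smiles"]:
        try:
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                out.append({"ok": False, "reason": "unparseable SMILES"})
                continue
            mol = rdMolStandardize.Cleanup(mol)
            mol = rdMolStandardize.FragmentParent(mol)
            mol = uncharger.uncharge(mol)
            out.append({"ok": True, "canonical": Chem.MolToSmiles(mol)})
        except Exception as exc:  # noqa: BLE001 - report, don't crash batch
            out.append({"ok": False, "reason": str(exc)})
    return out


def op_featurize(req):
    """Per-molecule atom and bond records for graph construction in R."""
    out = []
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append({"ok": False, "reason": "unparseable SMILES"})
            continue
        atoms = []
        for a in mol.GetAtoms():
            atoms.append(
                {
                    "symbol": a.GetSymbol(),
                    "degree": a.GetDegree(),
                    "charge": a.GetFormalCharge(),
                    "hybridization": HYB.get(a.GetHybridization(), "OTHER"),
                    "aromatic": bool(a.GetIsAromatic()),
                    "num_h": a.GetTotalNumHs(),
                    "chiral": CHIRAL.get(a.GetChiralTag(), "NONE"),
                }
            )
        bonds = []
        for b in mol.GetBonds():
            bonds.append(
                {
                    "begin": b.GetBeginAtomIdx(),
                    "end": b.GetEndAtomIdx(),
                    "type": BOND.get(b.GetBondType(), "OTHER"),
                    "conjugated": bool(b.GetIsConjugated()),
                    "in_ring": bool(b.IsInRing()),
                    "stereo": STEREO.get(b.GetStereo(), "NONE"),
                }
            )
        out.append({"ok": True, "n_atoms": mol.GetNumAtoms(),
                    "atoms": atoms, "bonds": bonds})
    return out


def op_fingerprints(req):
    """Morgan (radius/nbits) or MACCS on-bit indices (1-based for R)."""
    kind = req.get("kind", "morgan")
    out = []
    if kind == "morgan":
        gen = AllChem.GetMorganGenerator(
            radius=int(req.get("radius", 2)), fpSize=int(req.get("nbits", 2048))
        )
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append({"ok": False, "reason": "unparseable SMILES"})
            continue
        if kind == "morgan":
            fp = gen.GetFingerprint(mol)
        elif kind == "maccs":
            fp = MACCSkeys.GenMACCSKeys(mol)
        else:
            raise ValueError("unknown fingerprint kind: %s" % kind)
        out.append({"ok": True, "nbits": fp.GetNumBits(),
                    "onbits": [i + 1 for i in fp.GetOnBits()]})
    return out


def op_qed(req):
    out = []
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append({"ok": False, "reason": "unparseable SMILES"})
        else:
            out.append({"ok": True, "qed": QED.qed(mol)})
    return out


def op_smarts(req):
    """For each molecule x pattern: union of matched atom indices (1-based)
    and the number of distinct matches."""
    pats = []
    for s in req["smarts"]:
        p = Chem.MolFromSmarts(s)
        if p is None:
            raise ValueError("invalid SMARTS: %s" % s)
        pats.append(p)
    out = []
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append({"ok": False, "reason": "unparseable SMILES"})
            continue
        per_pat = []
        for p in pats:
            matches = mol.GetSubstructMatches(p)
            atoms = sorted({i + 1 for m in matches for i in m})
            per_pat.append({"n_matches": len(matches), "atoms": atoms})
        out.append({"ok": True, "patterns": per_pat})
    return out


def op_render(req):
    """SVG depiction with per-atom highlight intensity from weights in [0,1]."""
    smi = req["smiles"]
    weights = req["weights"]
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return {"ok": False, "reason": "unparseable SMILES"}
    if len(weights) != mol.GetNumAtoms():
        return {"ok": False, "reason": "weight length != atom count"}
    drawer = rdMolDraw2D.MolDraw2DSVG(
        int(req.get("width", 450)), int(req.get("height", 400))
    )
    colors = {
        i: (1.0 - 0.85 * w, 1.0, 1.0 - 0.85 * w)  # white -> green ramp
        for i, w in enumerate(weights)
    }
    rdMolDraw2D.PrepareAndDrawMolecule(
        drawer, mol,
        highlightAtoms=list(range(mol.GetNumAtoms())),
        highlightAtomColors=colors,
    )
    drawer.FinishDrawing()
    with open(req["out"], "w") as fh:
        fh.write(drawer.GetDrawingText())
    return {"ok": True, "path": req["out"]}


OPS = {
    "standardize": op_standardize,
    "featurize": op_featurize,
    "fingerprints": op_fingerprints,
    "qed": op_qed,
    "smarts": op_smarts,
    "render": op_render,
    "ping": lambda req: {"ok": True},
}


def main():
    with open(sys.argv[1]) as fh:
        req = json.load(fh)
    for key in ("smiles", "smarts"):
        # length-1 vectors arrive as bare strings from the JSON writer
        if key in req and isinstance(req[key], str) and req["op"] != "render":
            req[key] = [req[key]]
    result = OPS[req["op"]](req)
    with open(sys.argv[2], "w") as fh:
        json.dump(result, fh)


if __name__ == "__main__":
    main()
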