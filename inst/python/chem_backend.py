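#!/usr/bin/env python
"""Chemistry backend for the PharmSafe3D R package.

Reads one JSON request object on stdin, writes one JSON response on stdout.
All stochastic operations take explicit seeds; everything runs single-threaded
so results are reproducible bit-for-bit.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors
from rdkit.Chem import rdMolDescriptors
from rdkit.Chem.EnumerateStereoisomers import (EnumerateStereoisomers,
                                               StereoEnumerationOptions)
from rdkit.Chem.MolStandardize import rdMolStandardize

RDLogger.DisableLog("rdApp.*")


# ---------------------------------------------------------------- parse ----

def op_parse(req):
    out = []
    for sm in req["smiles"]:
        mol = Chem.MolFromSmiles(sm)
        if mol is None:
            out.append({"ok": False, "error": "unparsable SMILES"})
        else:
            out.append({
                "ok": True,
                "canonical": Chem.MolToSmiles(mol),
                "mw": Descriptors.MolWt(mol),
                "n_heavy": mol.GetNumHeavyAtoms(),
                "rotatable_bonds":
                    rdMolDescriptors.CalcNumRotatableBonds(mol),
            })
    return {"results": out}


# --------------------------------------------------------- standardize -----

# Rule table for ionization at pH ~7: (SMARTS, atom position in match,
# charge delta, H delta).  Deprotonations first, then protonations.
_IONIZATION_RULES = [
    # carboxylic acid -> carboxylate
    ("[CX3](=O)[OX2H1]", 2, -1, -1),
    # 1H/2H tetrazole -> tetrazolate
    ("[nX3H1]1nnnc1", 0, -1, -1),
    ("n1[nX3H1]nnc1", 1, -1, -1),
    # acyl sulfonamide N-H -> anion
    ("[SX4](=O)(=O)[NX3H1][CX3]=O", 3, -1, -1),
    # aliphatic amine -> ammonium (not aniline, amide, imine, hydrazine...)
    ("[NX3;H2,H1,H0;+0;!$(N[a]);!$(N[C,S,P]=[O,S,N]);!$(N=*);"
     "!$(N[O,N]);!$(N#*)]", 0, +1, +1),
    # amidine / guanidine: protonate the imino nitrogen
    ("[NX2;+0;!$(N[a])]=[CX3;$(C[#7])]", 0, +1, +1),
]


def _apply_ionization(mol):
    mol = Chem.RWMol(mol)
    touched = set()
    for smarts, pos, dq, dh in _IONIZATION_RULES:
        patt = Chem.MolFromSmarts(smarts)
        for match in mol.GetSubstructMatches(patt):
            idx = match[pos]
            if idx in touched:
                continue
            atom = mol.GetAtomWithIdx(idx)
            n_h = atom.GetTotalNumHs()
            if dh < 0 and n_h == 0:
                continue
            atom.SetFormalCharge(atom.GetFormalCharge() + dq)
            atom.SetNumExplicitHs(max(0, n_h + dh))
            atom.SetNoImplicit(True)
            touched.add(idx)
    m = mol.GetMol()
    Chem.SanitizeMol(m)
    return m


def op_standardize(req):
    max_isomers = int(req.get("max_isomers", 8))
    chooser = rdMolStandardize.LargestFragmentChooser(preferOrganic=True)
    out = []
    for rec in req["records"]:
        mol = Chem.MolFromSmiles(rec["smiles"])
        if mol is None:
            out.append({"id": rec["id"], "ok": False,
                        "error": "unparsable SMILES"})
            continue
        frag = chooser.choose(mol)
        if not any(a.GetSymbol() == "C" for a in frag.GetAtoms()):
            out.append({"id": rec["id"], "ok": False,
                        "error": "no organic fragment"})
            continue
        try:
            ion = _apply_ionization(frag)
        except Exception as exc:  # sanitization failure after charge edit
            out.append({"id": rec["id"], "ok": False, "error": str(exc)})
            continue
        opts = StereoEnumerationOptions(onlyUnassigned=True, unique=True,
                                        maxIsomers=max_isomers)
        isomers = list(EnumerateStereoisomers(ion, options=opts))
        if not isomers:
            isomers = [ion]
        children = []
        for j, iso in enumerate(sorted(Chem.MolToSmiles(m) for m in isomers)):
            m = Chem.MolFromSmiles(iso)
            cid = rec["id"] if len(isomers) == 1 else \
                "%s_s%d" % (rec["id"], j + 1)
            children.append({
                "id": cid,
                "smiles": iso,
                "mw": Descriptors.MolWt(m),
                "n_heavy": m.GetNumHeavyAtoms(),
                "rotatable_bonds": rdMolDescriptors.CalcNumRotatableBonds(m),
            })
        out.append({"id": rec["id"], "ok": True, "children": children,
                    "truncated": len(isomers) >= max_isomers})
    return {"results": out}


# --------------------------------------------------------------- embed -----

def _mol_topology(molh):
    atoms = []
    for a in molh.GetAtoms():
        atoms.append({
            "element": a.GetSymbol(),
            "charge": a.GetFormalCharge(),
            "aromatic": a.GetIsAromatic(),
            "in_ring": a.IsInRing(),
            "n_h": a.GetTotalNumHs(includeNeighbors=True),
        })
    bonds = [[b.GetBeginAtomIdx() + 1, b.GetEndAtomIdx() + 1,
              b.GetBondTypeAsDouble()] for b in molh.GetBonds()]
    ri = molh.GetRingInfo()
    arom_rings = []
    for ring in ri.AtomRings():
        if all(molh.GetAtomWithIdx(i).GetIsAromatic() for i in ring):
            arom_rings.append([i + 1 for i in ring])
    return atoms, bonds, arom_rings


def _do_matches(molh, smarts_map):
    res = {}
    for name, patterns in smarts_map.items():
        hits = []
        seen = set()
        for sm in patterns:
            patt = Chem.MolFromSmarts(sm)
            if patt is None:
                raise ValueError("malformed SMARTS: " + sm)
            for match in molh.GetSubstructMatches(patt, uniquify=True):
                key = tuple(sorted(match))
                if key not in seen:
                    seen.add(key)
                    hits.append([i + 1 for i in match])
        res[name] = hits
    return res


def op_embed(req):
    seed = int(req.get("seed", 1))
    smarts_map = req.get("smarts", {})
    out = []
    for rec in req["molecules"]:
        mol = Chem.MolFromSmiles(rec["smiles"])
        if mol is None:
            out.append({"id": rec["id"], "ok": False,
                        "error": "unparsable SMILES"})
            continue
        molh = Chem.AddHs(mol)
        atoms, bonds, arom_rings = _mol_topology(molh)
        entry = {"id": rec["id"], "ok": True, "atoms": atoms, "bonds": bonds,
                 "aromatic_rings": arom_rings,
                 "matches": _do_matches(molh, smarts_map) if smarts_map
                 else {}}
        n_conf = int(rec.get("n_conf", req.get("n_conf", 0)))
        if n_conf > 0:
            params = AllChem.ETKDGv3()
            params.randomSeed = seed + int(rec.get("seed_offset", 0))
            params.numThreads = 1
            cids = AllChem.EmbedMultipleConfs(molh, numConfs=n_conf,
                                              params=params)
            if len(cids) == 0:
                entry["ok"] = False
                entry["error"] = "embedding failed"
                out.append(entry)
                continue
            try:
                res = AllChem.MMFFOptimizeMoleculeConfs(molh, maxIters=1000,
                                                        numThreads=1)
                if any(e is None for _, e in res):
                    raise ValueError("MMFF parameters missing")
            except Exception:
                res = AllChem.UFFOptimizeMoleculeConfs(molh, maxIters=1000,
                                                       numThreads=1)
            confs = []
            for cid, (_, energy) in zip(cids, res):
                conf = molh.GetConformer(cid)
                coords = [[conf.GetAtomPosition(i).x,
                           conf.GetAtomPosition(i).y,
                           conf.GetAtomPosition(i).z]
                          for i in range(molh.GetNumAtoms())]
                confs.append({"energy": float(energy), "coords": coords})
            entry["conformers"] = confs
        out.append(entry)
    return {"results": out}


# --------------------------------------------------------- fingerprint -----

def op_fingerprint(req):
    radius = int(req.get("radius", 2))
    n_bits = int(req.get("n_bits", 1024))
    out = []
    for sm in req["smiles"]:
        mol = Chem.MolFromSmiles(sm)
        if mol is None:
            out.append({"ok": False, "error": "unparsable SMILES"})
            continue
        fp = AllChem.GetMorganFingerprintAsBitVect(mol, radius, nBits=n_bits)
        out.append({"ok": True, "bits": [b + 1 for b in fp.GetOnBits()]})
    return {"results": out}


# ----------------------------------------------------------------- sdf -----

def op_sdf_write(req):
    writer = Chem.SDWriter(req["path"])
    writer.SetKekulize(True)
    for rec in req["molecules"]:
        mol = Chem.MolFromSmiles(rec["smiles"])
        molh = Chem.AddHs(mol)
        for cf in rec["conformers"]:
            conf = Chem.Conformer(molh.GetNumAtoms())
            for i, xyz in enumerate(cf["coords"]):
                conf.SetAtomPosition(i, tuple(float(v) for v in xyz))
            m = Chem.Mol(molh)
            m.RemoveAllConformers()
            m.AddConformer(conf, assignId=True)
            m.SetProp("_Name", "%s_c%d" % (rec["id"], cf["conf_id"]))
            m.SetProp("parent_id", str(rec["parent_id"]))
            m.SetProp("rel_energy_kcal", "%.6f" % cf["rel_energy"])
            m.SetProp("conf_id", str(cf["conf_id"]))
            writer.write(m)
    writer.close()
    return {"ok": True}


def op_sdf_read(req):
    suppl = Chem.SDMolSupplier(req["path"], removeHs=False, sanitize=True)
    out = []
    for m in suppl:
        if m is None:
            out.append({"ok": False, "error": "unreadable SDF record"})
            continue
        conf = m.GetConformer()
        coords = [[conf.GetAtomPosition(i).x, conf.GetAtomPosition(i).y,
                   conf.GetAtomPosition(i).z] for i in range(m.GetNumAtoms())]
        props = {k: m.GetProp(k) for k in m.GetPropNames()}
        out.append({"ok": True, "name": m.GetProp("_Name"),
                    "elements": [a.GetSymbol() for a in m.GetAtoms()],
                    "coords": coords, "props": props,
                    "smiles": Chem.MolToSmiles(Chem.RemoveHs(m))})
    return {"results": out}


def op_check_smarts(req):
    out = []
    for sm in req["smarts"]:
        out.append({"ok": Chem.MolFromSmarts(sm) is not None})
    return {"results": out}


OPS = {"parse": op_parse, "standardize": op_standardize, "embed": op_embed,
       "fingerprint": op_fingerprint, "sdf_write": op_sdf_write,
       "sdf_read": op_sdf_read, "check_smarts": op_check_smarts}


def main():
    req = json.load(sys.stdin)
    op = req.get("op")
    if op not in OPS:
        json.dump({"ok": False, "error": "unknown op: %s" % op, "fatal": True},
                  sys.stdout)
        return 1
    try:
        resp = OPS[op](req)
    except Exception as exc:
        json.dump({"ok": False, "error": str(exc), "fatal": True}, sys.stdout)
        return 1
    json.dump(resp, sys.stdout)
    return 0


if __name__ == "__main__":
    sys.exit(main())
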