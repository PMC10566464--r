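"""Cheminformatics backend for the spinsys R package.

Reads a JSON request, performs RDKit operations (parsing, explicit-H
addition, Gasteiger charges, ETKDG conformer embedding with a single MMFF94
optimization step, stereoisomer enumeration, SDF export) and writes a JSON
response.  All heavy numeric work (featurization, modelling) lives on the R
side; this script only exposes raw atoms, bonds, coordinates and energies.

Usage: python chem_backend.py <request.json> <response.json>
"""

import json
import math
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem
from rdkit.Chem.EnumerateStereoisomers import (EnumerateStereoisomers,
                                               StereoEnumerationOptions)

RDLogger.DisableLog("rdApp.*")

PT = Chem.GetPeriodicTable()


def _atom_record(atom):
    gast = atom.GetDoubleProp("_GasteigerCharge") if atom.HasProp(
        "_GasteigerCharge") else 0.0
    if not math.isfinite(gast):
        gast = 0.0
    return {
        "element": atom.GetSymbol(),
        "atomic_num": atom.GetAtomicNum(),
        "formal_charge": atom.GetFormalCharge(),
        "gasteiger": round(gast, 6),
        "aromatic": bool(atom.GetIsAromatic()),
        "default_valence": PT.GetDefaultValence(atom.GetAtomicNum()),
        "total_valence": atom.GetTotalValence(),
        "degree": atom.GetDegree(),
        "n_h": atom.GetTotalNumHs(includeNeighbors=True),
        "ring_sizes": [k for k in range(3, 9) if atom.IsInRingSize(k)],
    }


def _bond_order(bond):
    bt = bond.GetBondType()
    if bt == Chem.BondType.SINGLE:
        return 1.0
    if bt == Chem.BondType.DOUBLE:
        return 2.0
    if bt == Chem.BondType.TRIPLE:
        return 3.0
    if bt == Chem.BondType.AROMATIC:
        return 1.5
    return None


def _mol_tables(mol):
    Chem.rdPartialCharges.ComputeGasteigerCharges(mol)
    atoms = [_atom_record(a) for a in mol.GetAtoms()]
    bonds = []
    for b in mol.GetBonds():
        order = _bond_order(b)
        if order is None:
            raise ValueError("unsupported bond order: %s" % b.GetBondType())
        bonds.append({
            "i": b.GetBeginAtomIdx(),
            "j": b.GetEndAtomIdx(),
            "order": order,
            "aromatic": bool(b.GetIsAromatic()),
        })
    return atoms, bonds


def _embed(mol, n_conf, seed, mmff_max_iters=1):
    """ETKDG embedding + MMFF94 optimization (default: a single step)."""
    params = AllChem.ETKDGv3()
    params.randomSeed = int(seed) % (2 ** 31 - 1)
    cids = AllChem.EmbedMultipleConfs(mol, numConfs=int(n_conf), params=params)
    if len(cids) == 0:
        params.useRandomCoords = True
        cids = AllChem.EmbedMultipleConfs(mol, numConfs=int(n_conf),
                                          params=params)
    if len(cids) == 0:
        return None, None, "embedding_failed"
    warn = None
    energies = []
    mmff_ok = AllChem.MMFFHasAllMoleculeParams(mol)
    props = AllChem.MMFFGetMoleculeProperties(mol) if mmff_ok else None
    for cid in cids:
        if mmff_ok:
            ff = AllChem.MMFFGetMoleculeForceField(mol, props, confId=cid)
            ff.Minimize(maxIts=int(mmff_max_iters), forceTol=1e-6,
                        energyTol=1e-12)
            energies.append(round(ff.CalcEnergy(), 6))
        else:
            energies.append(None)
    if not mmff_ok:
        warn = "mmff_unavailable"
        energies = None
    coords = []
    for cid in cids:
        conf = mol.GetConformer(cid)
        coords.append([[round(v, 9) for v in conf.GetAtomPosition(i)]
                       for i in range(mol.GetNumAtoms())])
    return coords, energies, warn


def _prepare(smiles=None, molblock=None):
    if smiles is not None:
        mol = Chem.MolFromSmiles(smiles)
    else:
        mol = Chem.MolFromMolBlock(molblock, removeHs=False)
    if mol is None:
        return None
    mol = Chem.AddHs(mol)
    Chem.AssignStereochemistry(mol, cleanIt=True, force=True)
    return mol


def op_parse(req):
    """Parse molecules; optionally embed conformers (n_conformers > 0)."""
    n_conf = int(req.get("n_conformers", 0))
    seed = int(req.get("seed", 0))
    mmff_max_iters = int(req.get("mmff_max_iters", 1))
    out = []
    records = req.get("smiles", [])
    molblocks = req.get("molblocks", [])
    items = ([("smiles", s) for s in records] +
             [("molblock", m) for m in molblocks])
    for idx, (kind, val) in enumerate(items):
        rec = {"input": val if kind == "smiles" else None}
        mol = _prepare(smiles=val if kind == "smiles" else None,
                       molblock=val if kind == "molblock" else None)
        if mol is None:
            rec["ok"] = False
            rec["error"] = "parse_error"
            out.append(rec)
            continue
        try:
            atoms, bonds = _mol_tables(mol)
        except ValueError as exc:
            rec["ok"] = False
            rec["error"] = str(exc)
            out.append(rec)
            continue
        rec.update({
            "ok": True,
            "canonical_smiles": Chem.MolToSmiles(Chem.RemoveHs(mol)),
            "atoms": atoms,
            "bonds": bonds,
        })
        if n_conf > 0:
            coords, energies, warn = _embed(mol, n_conf,
                                            seed * 7919 + idx,
                                            mmff_max_iters)
            if coords is None:
                rec["ok"] = False
                rec["error"] = warn
            else:
                rec["coords"] = coords
                rec["energies"] = energies
                if warn:
                    rec["warning"] = warn
        out.append(rec)
    return {"molecules": out}


def op_stereoisomers(req):
    cap = int(req.get("max_candidates", 8))
    out = []
    for smi in req.get("smiles", []):
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append({"ok": False, "error": "parse_error"})
            continue
        Chem.AssignStereochemistry(mol, cleanIt=True, force=True)
        input_canonical = Chem.MolToSmiles(mol)
        opts = StereoEnumerationOptions(onlyUnassigned=False, unique=True,
                                        maxIsomers=max(256, cap))
        isomers = sorted({Chem.MolToSmiles(m)
                          for m in EnumerateStereoisomers(mol, options=opts)})
        if input_canonical in isomers:
            isomers.remove(input_canonical)
        candidates = ([input_canonical] + isomers)[:cap]
        out.append({"ok": True, "input": input_canonical,
                    "candidates": candidates})
    return {"molecules": out}


def op_write_sdf(req):
    """Serialize SMILES to a V2000 SDF string (explicit H, 2D coords)."""
    blocks = []
    for smi in req.get("smiles", []):
        mol = _prepare(smiles=smi)
        if mol is None:
            blocks.append(None)
            continue
        AllChem.Compute2DCoords(mol)
        blocks.append(Chem.MolToMolBlock(mol, kekulize=True))
    return {"molblocks": blocks}


OPS = {"parse": op_parse, "stereoisomers": op_stereoisomers,
       "write_sdf": op_write_sdf}


def main():
    req_path, res_path = sys.argv[1], sys.argv[2]
    with open(req_path) as fh:
        req = json.load(fh)
    res = OPS[req["op"]](req)
    with open(res_path, "w") as fh:
        json.dump(res, fh)


if __name__ == "__main__":
    main()
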