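#!/usr/bin/env python
"""Convert a nested-struct MATLAB experiment container to JSON.

Supports both the legacy (v7 and earlier, via scipy.io) and the
HDF5-based (v7.3, via h5py) .mat dialects.  The output is a plain JSON
tree: structs become objects, cell arrays become lists, numeric arrays
become (nested) lists, MATLAB strings become JSON strings.  NaN is
emitted as the string "NaN" (JSON has no NaN literal).

Usage: python mat_to_json.py <input.mat> <output.json>
"""
import json
import sys

import numpy as np


def _clean_scalar(x):
    if isinstance(x, (np.floating, float)):
        x = float(x)
        if x != x:
            return "NaN"
        return x
    if isinstance(x, (np.integer, int)):
        return int(x)
    if isinstance(x, (np.bool_, bool)):
        return bool(x)
    if isinstance(x, (bytes, np.bytes_)):
        return x.decode("utf-8", "replace")
    return x


def _clean_array(a):
    a = np.asarray(a)
    if a.size == 0:
        return []
    if a.ndim == 0:
        return _clean_scalar(a.item())
    return [_clean_array(x) if isinstance(x, np.ndarray) else _clean_scalar(x)
            for x in a]


# ---------------------------------------------------------------- scipy path

def convert_scipy(obj):
    import scipy.io.matlab as siom
    if isinstance(obj, siom.mat_struct):
        return {f: convert_scipy(getattr(obj, f)) for f in obj._fieldnames}
    if isinstance(obj, np.ndarray):
        if obj.dtype == object:
            return [convert_scipy(x) for x in obj.ravel(order="F")]
        return _clean_array(obj)
    if isinstance(obj, str):
        return obj
    return _clean_scalar(obj)


def load_scipy(path):
    from scipy.io import loadmat
    d = loadmat(path, squeeze_me=True, struct_as_record=False)
    return {k: convert_scipy(v) for k, v in d.items()
            if not k.startswith("__")}


# ----------------------------------------------------------------- h5py path

def _h5_string(ds):
    data = np.asarray(ds)
    # MATLAB stores char arrays as uint16 code units
    return "".join(chr(int(c)) for c in data.ravel(order="F"))


def convert_h5(obj, f):
    import h5py
    if isinstance(obj, h5py.Group):
        return {k: convert_h5(obj[k], f) for k in obj.keys()
                if not k.startswith("#")}
    if isinstance(obj, h5py.Dataset):
        cls = obj.attrs.get("MATLAB_class", b"")
        if isinstance(cls, bytes):
            cls = cls.decode()
        if cls == "char":
            return _h5_string(obj)
        data = obj[()]
        if isinstance(data, np.ndarray) and data.dtype == h5py.ref_dtype:
            return [convert_h5(f[r], f) for r in data.ravel(order="F")]
        if isinstance(data, h5py.Reference):
            return convert_h5(f[data], f)
        if isinstance(data, np.ndarray):
            data = np.squeeze(data.T)  # MATLAB is column-major
            return _clean_array(data)
        return _clean_scalar(data)
    return None


def load_h5(path):
    import h5py
    with h5py.File(path, "r") as f:
        return {k: convert_h5(f[k], f) for k in f.keys()
                if not k.startswith("#")}


def main(argv):
    if len(argv) != 3:
        sys.exit(__doc__)
    src, dst = argv[1], argv[2]
    try:
        tree = load_scipy(src)
    except (NotImplementedError, ValueError):
        # v7.3 containers are HDF5; scipy raises on them
        tree = load_h5(src)
    with open(dst, "w") as fh:
        json.dump(tree, fh)


if __name__ == "__main__":
    main(sys.argv)
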