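"""Tiny HDF5 Scientific-Data-Exchange bridge.

write <h5> <rawf32> <nangle> <nrow> <ncol> <theta-csv> <units>
    raw little-endian float32 (C-order angle,row,col) -> /exchange/data,
    theta values -> /exchange/theta with a `units` attribute.
read <h5> <rawf32-out>
    dumps /exchange/data to raw float32 and prints a JSON header
    {"shape": [...], "theta": [...], "units": "..."} on stdout.
"""
import json
import sys

import h5py
import numpy as np


def main(argv):
    mode = argv[1]
    if mode == "write":
        path, rawf, na, nr, nc, theta_csv, units = argv[2:9]
        shape = (int(na), int(nr), int(nc))
        data = np.fromfile(rawf, dtype="<f4").reshape(shape)
        theta = np.array([float(x) for x in theta_csv.split(",")])
        with h5py.File(path, "w") as f:
            f.create_dataset("/exchange/data", data=data)
            d = f.create_dataset("/exchange/theta", data=theta)
            d.attrs["units"] = units
    elif mode == "read":
        path, rawf = argv[2:4]
        with h5py.File(path, "r") as f:
            data = f["/exchange/data"][...]
            theta = f["/exchange/theta"][...]
            units = f["/exchange/theta"].attrs.get("units", "degree")
            if isinstance(units, bytes):
                units = units.decode()
        data.astype("<f4").tofile(rawf)
        print(json.dumps({"shape": list(data.shape),
                          "theta": [float(t) for t in theta],
                          "units": str(units)}))
    else:
        raise SystemExit("unknown mode " + mode)


if __name__ == "__main__":
    main(sys.argv)
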