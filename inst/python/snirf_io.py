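"""Minimal SNIRF (HDF5) bridge.

Converts between a JSON recording payload and a continuous-wave SNIRF
file. Invoked by the R package as:

    python snirf_io.py write <payload.json> <out.snirf>
    python snirf_io.py read  <in.snirf>    <payload.json>

The JSON payload holds: fs, subject_age, wavelengths, channels
(source_id, detector_id, distance_mm, is_short), roi_channels, stim
(name, onsets, task_duration, rest_duration), intensity as a list of
per-channel-per-wavelength columns in column order ch1_w1, ch1_w2,
ch2_w1, ... (wavelengths ascending).
"""
import json
import sys

import h5py
import numpy as np


def _str(ds):
    v = ds[()]
    if isinstance(v, bytes):
        return v.decode()
    if isinstance(v, np.ndarray):
        v = v.item()
        if isinstance(v, bytes):
            return v.decode()
    return str(v)


def write_snirf(payload_path, out_path):
    with open(payload_path) as fh:
        p = json.load(fh)
    wl = np.asarray(p["wavelengths"], dtype=float)
    ch = p["channels"]
    n_ch = len(ch["source_id"])
    cols = np.asarray(p["intensity"], dtype=float)  # [n_ch*2][T]
    T = cols.shape[1]
    data = cols.T  # [T, M] with M = n_ch*2, channel-major, wavelength minor

    with h5py.File(out_path, "w") as f:
        f.create_dataset("formatVersion", data="1.0")
        nirs = f.create_group("/nirs")
        meta = nirs.create_group("metaDataTags")
        meta.create_dataset("SubjectID", data="sim")
        meta.create_dataset("MeasurementDate", data="1970-01-01")
        meta.create_dataset("MeasurementTime", data="00:00:00")
        meta.create_dataset("LengthUnit", data="mm")
        meta.create_dataset("TimeUnit", data="s")
        meta.create_dataset("FrequencyUnit", data="Hz")
        meta.create_dataset("SubjectAge", data=str(p["subject_age"]))
        meta.create_dataset("RoiChannels",
                            data=",".join(str(i) for i in p["roi_channels"]))
        meta.create_dataset("RestDuration", data=str(p["stim"]["rest_duration"]))

        d1 = nirs.create_group("data1")
        d1.create_dataset("dataTimeSeries", data=data)
        d1.create_dataset("time", data=np.arange(T) / p["fs"])
        m = 0
        for c in range(n_ch):
            for w in range(2):
                m += 1
                ml = d1.create_group("measurementList%d" % m)
                ml.create_dataset("sourceIndex", data=int(c + 1))
                ml.create_dataset("detectorIndex", data=int(c + 1))
                ml.create_dataset("wavelengthIndex", data=int(w + 1))
                ml.create_dataset("dataType", data=1)
                ml.create_dataset("dataTypeIndex", data=1)

        probe = nirs.create_group("probe")
        probe.create_dataset("wavelengths", data=wl)
        # geometry encodes each channel's distance on the x axis
        spos = np.zeros((n_ch, 2))
        dpos = np.zeros((n_ch, 2))
        for c in range(n_ch):
            spos[c, 1] = 40.0 * c
            dpos[c, 0] = float(ch["distance_mm"][c])
            dpos[c, 1] = 40.0 * c
        probe.create_dataset("sourcePos2D", data=spos)
        probe.create_dataset("detectorPos2D", data=dpos)

        stim = nirs.create_group("stim1")
        stim.create_dataset("name", data=p["stim"].get("name", "Tap"))
        onsets = np.asarray(p["stim"]["onsets"], dtype=float)
        sdata = np.column_stack([onsets,
                                 np.full(len(onsets), p["stim"]["task_duration"]),
                                 np.ones(len(onsets))])
        stim.create_dataset("data", data=sdata)


def read_snirf(in_path, payload_path):
    with h5py.File(in_path, "r") as f:
        nirs = f["/nirs"] if "/nirs" in f else f["/nirs1"]
        d1 = nirs["data1"]
        data = np.asarray(d1["dataTimeSeries"])
        time = np.asarray(d1["time"]).ravel()
        if len(time) == 2:  # start/step encoding
            fs = 1.0 / float(time[1] - time[0])
        else:
            fs = 1.0 / float(np.median(np.diff(time)))
        probe = nirs["probe"]
        wl = np.asarray(probe["wavelengths"], dtype=float).ravel()
        if wl.size != 2:
            raise SystemExit("unsupported-format: need exactly 2 wavelengths, "
                             "found %d" % wl.size)
        order = np.argsort(wl)

        mls = sorted((k for k in d1 if k.startswith("measurementList")),
                     key=lambda k: int(k[len("measurementList"):]))
        entries = []
        for k in mls:
            g = d1[k]
            entries.append((int(np.asarray(g["sourceIndex"])),
                            int(np.asarray(g["detectorIndex"])),
                            int(np.asarray(g["wavelengthIndex"]))))
        pairs = sorted(set((s, d) for s, d, _ in entries))
        n_ch = len(pairs)

        spos_name = "sourcePos2D" if "sourcePos2D" in probe else "sourcePos3D"
        dpos_name = "detectorPos2D" if "detectorPos2D" in probe else "detectorPos3D"
        spos = np.asarray(probe[spos_name], dtype=float)
        dpos = np.asarray(probe[dpos_name], dtype=float)

        cols = []
        dist = []
        for (s, d) in pairs:
            dist.append(float(np.linalg.norm(spos[s - 1] - dpos[d - 1])))
            for wi in order:
                idx = entries.index((s, d, int(wi) + 1))
                cols.append(data[:, idx].tolist())

        meta = nirs["metaDataTags"]
        age = float(_str(meta["SubjectAge"])) if "SubjectAge" in meta else 30.0
        roi = []
        if "RoiChannels" in meta:
            txt = _str(meta["RoiChannels"])
            roi = [int(x) for x in txt.split(",") if x.strip()]
        rest = float(_str(meta["RestDuration"])) if "RestDuration" in meta else 15.0

        stim_keys = [k for k in nirs if k.startswith("stim")]
        if not stim_keys:
            raise SystemExit("unsupported-format: no stimulus group")
        sg = nirs[sorted(stim_keys)[0]]
        sdata = np.atleast_2d(np.asarray(sg["data"], dtype=float))
        payload = {
            "fs": fs,
            "subject_age": age,
            "wavelengths": np.sort(wl).tolist(),
            "channels": {
                "source_id": [s for s, _ in pairs],
                "detector_id": [d for _, d in pairs],
                "distance_mm": dist,
                "is_short": [x <= 20.0 for x in dist],
            },
            "roi_channels": roi,
            "stim": {
                "name": _str(sg["name"]) if "name" in sg else "stim",
                "onsets": sdata[:, 0].tolist(),
                "task_duration": float(sdata[0, 1]),
                "rest_duration": rest,
            },
            "intensity": cols,
        }
    with open(payload_path, "w") as fh:
        json.dump(payload, fh)


def main():
    mode, src, dst = sys.argv[1], sys.argv[2], sys.argv[3]
    if mode == "write":
        write_snirf(src, dst)
    elif mode == "read":
        read_snirf(src, dst)
    else:
        raise SystemExit("unknown mode: %s" % mode)


if __name__ == "__main__":
    main()
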