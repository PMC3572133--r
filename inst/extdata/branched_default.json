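{
  "id": "branched",
  "states": [
    "DD",
    "ED",
    "TD",
    "DT",
    "DE",
    "EE"
  ],
  "transitions": [
    {
      "from": "DD",
      "to": "ED",
      "rate": "adp_release_trail",
      "law": {
        "type": "release",
        "species": "ADP"
      },
      "offset": 0,
      "cycles": [
        "F"
      ]
    },
    {
      "from": "ED",
      "to": "DD",
      "rate": "adp_bind",
      "law": {
        "type": "binding",
        "species": "ADP"
      },
      "offset": 0,
      "cycles": [
        "F"
      ]
    },
    {
      "from": "ED",
      "to": "TD",
      "rate": "atp_bind",
      "law": {
        "type": "binding",
        "species": "ATP"
      },
      "offset": 0,
      "cycles": [
        "F"
      ]
    },
    {
      "from": "TD",
      "to": "ED",
      "rate": "atp_dissoc",
      "law": {
        "type": "release",
        "species": "ATP"
      },
      "offset": 0,
      "cycles": [
        "F"
      ]
    },
    {
      "from": "TD",
      "to": "DT",
      "rate": "step_fwd",
      "law": {
        "type": "mechanical",
        "direction": "forward"
      },
      "offset": 1,
      "cycles": [
        "F"
      ]
    },
    {
      "from": "DT",
      "to": "TD",
      "rate": "step_bwd",
      "law": {
        "type": "mechanical",
        "direction": "backward"
      },
      "offset": -1,
      "cycles": [
        "F"
      ]
    },
    {
      "from": "DT",
      "to": "DD",
      "rate": "p_release",
      "law": {
        "type": "release",
        "species": "P"
      },
      "offset": 0,
      "cycles": [
        "F"
      ]
    },
    {
      "from": "DD",
      "to": "DT",
      "rate": "p_bind",
      "law": {
        "type": "binding",
        "species": "P"
      },
      "offset": 0,
      "cycles": [
        "F"
      ]
    },
    {
      "from": "DD",
      "to": "DE",
      "rate": "adp_release_lead",
      "law": {
        "type": "release",
        "species": "ADP"
      },
      "offset": 0,
      "cycles": [
        "E"
      ]
    },
    {
      "from": "ED",
      "to": "EE",
      "rate": "adp_release_lead",
      "law": {
        "type": "release",
        "species": "ADP"
      },
      "offset": 0,
      "cycles": [
        "E"
      ]
    },
    {
      "from": "DE",
      "to": "EE",
      "rate": "adp_release_trail",
      "law": {
        "type": "release",
        "species": "ADP"
      },
      "offset": 0,
      "cycles": [
        "E"
      ]
    },
    {
      "from": "EE",
      "to": "ED",
      "rate": "adp_bind",
      "law": {
        "type": "binding",
        "species": "ADP"
      },
      "offset": 0,
      "cycles": [
        "E"
      ]
    },
    {
      "from": "EE",
      "to": "DE",
      "rate": "adp_bind",
      "law": {
        "type": "binding",
        "species": "ADP"
      },
      "offset": 0,
      "cycles": [
        "E"
      ]
    },
    {
      "from": "DE",
      "to": "DD",
      "rate": "adp_bind",
      "law": {
        "type": "binding",
        "species": "ADP"
      },
      "offset": 0,
      "cycles": [
        "E"
      ]
    },
    {
      "from": "EE",
      "to": "EE",
      "rate": "slip_fwd",
      "law": {
        "type": "mechanical",
        "direction": "forward",
        "slip": true
      },
      "offset": 1,
      "cycles": [
        "M"
      ]
    },
    {
      "from": "EE",
      "to": "EE",
      "rate": "slip_bwd",
      "law": {
        "type": "mechanical",
        "direction": "backward",
        "slip": true
      },
      "offset": -1,
      "cycles": [
        "M"
      ]
    }
  ]
}
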