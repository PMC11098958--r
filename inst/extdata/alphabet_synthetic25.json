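{
  "letters": ["A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K", "L", "M", "N", "O", "P", "Q", "R", "S", "T", "U", "V", "W", "X", "Y"],
  "coords": [
    [
      [0, 0, 0],
      [3.8, 0, 0],
      [3.73368085553832, 3.79942124159429, 0],
      [7.17271375457398, 3.99208807306058, -1.60497109363476]
    ],
    [
      [0, 0, 0],
      [3.8, 0, 0],
      [6.48700576850888, 2.68700576850888, 0],
      [7.34427679135186, 5.28408277597343, -2.63823376725656]
    ],
    [
      [0, 0, 0],
      [3.8, 0, 0],
      [4.78351237138958, 3.67051813989846, 0],
      [1.67821714985022, 5.18572001078888, 1.58155141476178]
    ],
    [
      [0, 0, 0],
      [3.8, 0, 0],
      [5.7, 3.29089653438087, 0],
      [7.34404366651197, 4.40168393291062, 3.24087515616837]
    ],
    [
      [0, 0, 0],
      [3.8, 0, 0],
      [4.1311918224411, 3.78553985274863, 0],
      [7.42208835682197, 5.68553985274863, 3.81205333040339e-16]
    ],
    [
      [0, 0, 0],
      [3.8, 0, 0],
      [3.99887663372319, 3.79479223206738, 0],
      [2.38916440276934, 3.74635359000533, -3.44187161751754]
    ],
    [
      [0, 0, 0],
      [3.8, 0, 0],
      [6.66789640484653, 2.49302431016393, 0],
      [6.52567231625381, 6.06118165190923, 1.29924035234942]
    ],
    [
      [0, 0, 0],
      [3.8, 0, 0],
      [5.03715898693719, 3.5929705872774, 0],
      [6.09131228159211, 3.65009206448066, 3.65041065747545]
    ],
    [
      [0, 0, 0],
      [3.8, 0, 0],
      [5.92493303318884, 3.15034277570916, 0],
      [9.66720249463523, 2.49047970057482, 4.25132797819494e-16]
    ],
    [
      [0, 0, 0],
      [3.8, 0, 0],
      [4.39445096715288, 3.75321569426152, 0],
      [7.61632923260821, 5.22446104773138, -1.37656730764604]
    ],
    [
      [0, 0, 0],
      [3.8, 0, 0],
      [3.4688081775589, 3.78553985274863, 0],
      [0.0221195919492407, 3.88271910586435, 1.5971518357977]
    ],
    [
      [0, 0, 0],
      [3.8, 0, 0],
      [6.29302431016393, 2.86789640484653, 0],
      [8.55876614152512, 4.39595627335619, 2.64034978589396]
    ],
    [
      [0, 0, 0],
      [3.8, 0, 0],
      [4.52507418243087, 3.73018329710112, 0],
      [8.31986641449825, 3.92905993082431, 4.51542431055897e-16]
    ],
    [
      [0, 0, 0],
      [3.8, 0, 0],
      [5.46581035779849, 3.41541737593683, 0],
      [8.97361985522453, 3.9449833359493, -1.36192232662653]
    ],
    [
      [0, 0, 0],
      [3.8, 0, 0],
      [3.86631914446168, 3.79942124159429, 0],
      [2.66018813319869, 6.21225610264501, -2.67646705882364]
    ],
    [
      [0, 0, 0],
      [3.8, 0, 0],
      [4.26310350493956, 3.77167537623702, 0],
      [5.18552980259417, 3.25822454394157, 3.65041065747544]
    ],
    [
      [0, 0, 0],
      [3.8, 0, 0],
      [6.83481493817971, 2.28689708797778, 0],
      [10.3824205588691, 0.925098879705641, 3.9465256686277e-16]
    ],
    [
      [0, 0, 0],
      [3.8, 0, 0],
      [5.28477828825924, 3.49791844311927, 0],
      [8.50485583211938, 2.2751476550627, -1.60497109363476]
    ],
    [
      [0, 0, 0],
      [3.8, 0, 0],
      [6.1395136062375, 2.99444086370554, 0],
      [5.75048830606596, 4.94769394792466, -3.23627281062876]
    ],
    [
      [0, 0, 0],
      [3.8, 0, 0],
      [4.65481400650669, 3.70260624618389, 0],
      [2.05294007321734, 6.07383897087027, 1.43091138811802]
    ],
    [
      [0, 0, 0],
      [3.8, 0, 0],
      [3.20554903284712, 3.75321569426152, 0],
      [6.79851962012453, 4.99037468119872, 4.58295831750721e-16]
    ],
    [
      [0, 0, 0],
      [3.8, 0, 0],
      [6.08689708797778, 3.03481493817971, 0],
      [9.62682077376681, 3.9032600212858, -1.07458989220015]
    ],
    [
      [0, 0, 0],
      [3.8, 0, 0],
      [4.26310350493956, 3.77167537623702, 0],
      [2.89024634665992, 5.12332414025158, -3.27540972119494]
    ],
    [
      [0, 0, 0],
      [3.8, 0, 0],
      [5.22350505498047, 3.52329864735379, 0],
      [3.47687292941932, 6.63798173312427, 1.29924035234942]
    ],
    [
      [0, 0, 0],
      [3.8, 0, 0],
      [3.60112336627681, 3.79479223206738, 0],
      [4.1837994722616, 6.4204793243969, 2.68444702847505]
    ]
  ],
  "angles": [
    {
      "theta1": 89,
      "theta2": 92,
      "tau": -155
    },
    {
      "theta1": 135,
      "theta2": 130,
      "tau": -65
    },
    {
      "theta1": 105,
      "theta2": 100,
      "tau": 25
    },
    {
      "theta1": 120,
      "theta2": 118,
      "tau": 105
    },
    {
      "theta1": 95,
      "theta2": 125,
      "tau": 180
    },
    {
      "theta1": 93,
      "theta2": 88,
      "tau": -65
    },
    {
      "theta1": 139,
      "theta2": 126,
      "tau": 25
    },
    {
      "theta1": 109,
      "theta2": 96,
      "tau": 105
    },
    {
      "theta1": 124,
      "theta2": 114,
      "tau": 180
    },
    {
      "theta1": 99,
      "theta2": 121,
      "tau": -155
    },
    {
      "theta1": 85,
      "theta2": 96,
      "tau": 25
    },
    {
      "theta1": 131,
      "theta2": 134,
      "tau": 105
    },
    {
      "theta1": 101,
      "theta2": 104,
      "tau": 180
    },
    {
      "theta1": 116,
      "theta2": 122,
      "tau": -155
    },
    {
      "theta1": 91,
      "theta2": 129,
      "tau": -65
    },
    {
      "theta1": 97,
      "theta2": 84,
      "tau": 105
    },
    {
      "theta1": 143,
      "theta2": 122,
      "tau": 180
    },
    {
      "theta1": 113,
      "theta2": 92,
      "tau": -155
    },
    {
      "theta1": 128,
      "theta2": 110,
      "tau": -65
    },
    {
      "theta1": 103,
      "theta2": 117,
      "tau": 25
    },
    {
      "theta1": 81,
      "theta2": 100,
      "tau": 180
    },
    {
      "theta1": 127,
      "theta2": 138,
      "tau": -155
    },
    {
      "theta1": 97,
      "theta2": 108,
      "tau": -65
    },
    {
      "theta1": 112,
      "theta2": 126,
      "tau": 25
    },
    {
      "theta1": 87,
      "theta2": 133,
      "tau": 105
    }
  ]
}
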