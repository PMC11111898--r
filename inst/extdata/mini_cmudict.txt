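;;; Mini pronouncing lexicon in CMU dictionary format.
;;; Curated subset for testing and simulation: covers all 39 stress-stripped
;;; ARPAbet phonemes and all scoring worked examples.
ABOUT  AH0 B AW1 T
AFTER  AE1 F T ER0
ALTHOUGH  AO2 L DH OW1
ANSWER  AE1 N S ER0
APPLE  AE1 P AH0 L
BASKET  B AE1 S K AH0 T
BATH  B AE1 TH
BEACH  B IY1 CH
BED  B EH1 D
BIG  B IH1 G
BIRD  B ER1 D
BLUE  B L UW1
BOAT  B OW1 T
BOOK  B UH1 K
BOOT  B UW1 T
BOOTH  B UW1 TH
BOTTLE  B AA1 T AH0 L
BOY  B OY1
BREAD  B R EH1 D
BROTHER  B R AH1 DH ER0
BROWN  B R AW1 N
CAGE  K EY1 JH
CAKE  K EY1 K
CAMP  K AE1 M P
CAT  K AE1 T
CATCH  K AE1 CH
CHAIR  CH EH1 R
CHANGE  CH EY1 N JH
CHEESE  CH IY1 Z
CHIEF  CH IY1 F
CHILD  CH AY1 L D
CHURCH  CH ER1 CH
CLOCK  K L AA1 K
CLOUD  K L AW1 D
COIN  K OY1 N
COLD  K OW1 L D
CORN  K AO1 R N
COUCH  K AW1 CH
CROWD  K R AW1 D
CUP  K AH1 P
DANCE  D AE1 N S
DAY  D EY1
DEEP  D IY1 P
DISH  D IH1 SH
DOG  D AO1 G
DOOR  D AO1 R
DOWN  D AW1 N
DREAM  D R IY1 M
DRESS  D R EH1 S
EARTH  ER1 TH
ECHOES  EH1 K OW0 Z
ECHOS  EH1 K OW0 Z
ECHOS(2)  EH1 K OW0 S
EIGHT  EY1 T
ESSAY  EH1 S EY2
ETHIC  EH1 TH IH0 K
FACE  F EY1 S
FARM  F AA1 R M
FATHER  F AA1 DH ER0
FEATHER  F EH1 DH ER0
FENCE  F EH1 N S
FIELD  F IY1 L D
FISH  F IH1 SH
FIVE  F AY1 V
FLOWER  F L AW1 ER0
FOOD  F UW1 D
FOOT  F UH1 T
FOREST  F AO1 R AH0 S T
FOUR  F AO1 R
FOX  F AA1 K S
FRESH  F R EH1 SH
FROG  F R AO1 G
GARDEN  G AA1 R D AH0 N
GATE  G EY1 T
GIFT  G IH1 F T
GIRL  G ER1 L
GLASS  G L AE1 S
GOLD  G OW1 L D
GOOD  G UH1 D
GREEN  G R IY1 N
GROUND  G R AW1 N D
HAND  HH AE1 N D
HEART  HH AA1 R T
HILL  HH IH1 L
HOLE  HH OW1 L
HOME  HH OW1 M
HORSE  HH AO1 R S
HOT  HH AA1 T
HOUSE  HH AW1 S
JUDGE  JH AH1 JH
JUICE  JH UW1 S
JUMP  JH AH1 M P
JUNE  JH UW1 N
KING  K IH1 NG
KITCHEN  K IH1 CH AH0 N
KNIFE  N AY1 F
LAKE  L EY1 K
LAMP  L AE1 M P
LARGE  L AA1 R JH
LEAF  L IY1 F
LEATHER  L EH1 DH ER0
LIGHT  L AY1 T
LION  L AY1 AH0 N
LOATHE  L OW1 DH
LUNCH  L AH1 N CH
MEASURE  M EH1 ZH ER0
MILK  M IH1 L K
MIRROR  M IH1 R ER0
MONTH  M AH1 N TH
MOON  M UW1 N
MORNING  M AO1 R N IH0 NG
MOTHER  M AH1 DH ER0
MOUNTAIN  M AW1 N T AH0 N
MOUSE  M AW1 S
MOUTH  M AW1 TH
MUSIC  M Y UW1 Z IH0 K
NIGHT  N AY1 T
NORTH  N AO1 R TH
NOSE  N OW1 Z
OCEAN  OW1 SH AH0 N
ORANGE  AO1 R AH0 N JH
OTHER  AH1 DH ER0
PAPER  P EY1 P ER0
PARK  P AA1 R K
PATH  P AE1 TH
PEACE  P IY1 S
PENCIL  P EH1 N S AH0 L
PHONE  F OW1 N
PICTURE  P IH1 K CH ER0
PLANE  P L EY1 N
PLANT  P L AE1 N T
PLEASURE  P L EH1 ZH ER0
POINT  P OY1 N T
POLICY  P AA1 L AH0 S IY0
POLISH  P AA1 L IH0 SH
POOL  P UW1 L
PUSH  P UH1 SH
PUT  P UH1 T
QUEEN  K W IY1 N
QUESTION  K W EH1 S CH AH0 N
RAIN  R EY1 N
RED  R EH1 D
RICH  R IH1 CH
RING  R IH1 NG
RIVER  R IH1 V ER0
ROAD  R OW1 D
ROCK  R AA1 K
ROOF  R UW1 F
ROUND  R AW1 N D
SCHOOL  S K UW1 L
SEA  S IY1
SEVEN  S EH1 V AH0 N
SHAPE  SH EY1 P
SHEEP  SH IY1 P
SHIP  SH IH1 P
SHOE  SH UW1
SHOWER  SH AW1 ER0
SING  S IH1 NG
SISTER  S IH1 S T ER0
SIX  S IH1 K S
SMALL  S M AO1 L
SMOOTH  S M UW1 DH
SNAKE  S N EY1 K
SONG  S AO1 NG
SOUTH  S AW1 TH
SPOON  S P UW1 N
SPOUT  S P AW1 T
SPRING  S P R IH1 NG
STAR  S T AA1 R
STONE  S T OW1 N
STORM  S T AO1 R M
STREET  S T R IY1 T
STRONG  S T R AO1 NG
SUGAR  SH UH1 G ER0
SUMMER  S AH1 M ER0
SUN  S AH1 N
TABLE  T EY1 B AH0 L
TALK  T AO1 K
TEACHER  T IY1 CH ER0
THANK  TH AE1 NG K
THEME  TH IY1 M
THICK  TH IH1 K
THIN  TH IH1 N
THING  TH IH1 NG
THIS  DH IH1 S
THREE  TH R IY1
THUMB  TH AH1 M
TIME  T AY1 M
TOOTH  T UW1 TH
TOWER  T AW1 ER0
TOWN  T AW1 N
TRAIN  T R EY1 N
TREASURE  T R EH1 ZH ER0
TREE  T R IY1
TRUCK  T R AH1 K
USUAL  Y UW1 ZH AH0 W AH0 L
VILLAGE  V IH1 L AH0 JH
VISION  V IH1 ZH AH0 N
VOICE  V OY1 S
WAR  W AO1 R
WATCH  W AA1 CH
WATER  W AO1 T ER0
WEATHER  W EH1 DH ER0
WHALE  W EY1 L
WHEEL  W IY1 L
WHITE  W AY1 T
WINDOW  W IH1 N D OW0
WINTER  W IH1 N T ER0
WOMAN  W UH1 M AH0 N
WOOD  W UH1 D
WORE  W AO1 R
WORM  W ER1 M
WORMHOLE  W ER1 M HH OW2 L
YARD  Y AA1 R D
YELLOW  Y EH1 L OW0
YES  Y EH1 S
YOUNG  Y AH1 NG
ZEBRA  Z IY1 B R AH0
ZONE  Z OW1 N
ZOO  Z UW1
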